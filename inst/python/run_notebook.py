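"""Single-pass notebook runner.

Usage: python run_notebook.py NB_PATH OUT_NB OUT_TRACE TIMEOUT_SECONDS

Executes every code cell of an ipynb document exactly once, top to bottom, in
one shared namespace with the working directory set to the notebook's
directory. Captured stdout/stderr become stream outputs; execution stops at
the first raised exception, whose class name (ename) is recorded verbatim.
A SIGALRM wall-clock timeout aborts the run and marks it timed out. Only the
standard library is used.
"""
import contextlib
import io
import json
import os
import signal
import sys
import time
import traceback


class _NotebookTimeout(Exception):
    pass


def _on_alarm(signum, frame):
    raise _NotebookTimeout()


def _source(cell):
    src = cell.get("source", "")
    if isinstance(src, list):
        src = "".join(src)
    return src


def _strip_directives(src):
    out = []
    for line in src.split("\n"):
        ls = line.lstrip()
        if ls.startswith("%") or ls.startswith("!") or line.rstrip().endswith("?"):
            out.append("")
        else:
            out.append(line)
    return "\n".join(out)


def main():
    nb_path, out_nb, out_trace, timeout = (
        sys.argv[1], sys.argv[2], sys.argv[3], float(sys.argv[4]))
    with open(nb_path, encoding="utf-8") as fh:
        nb = json.load(fh)

    nb_dir = os.path.dirname(os.path.abspath(nb_path))
    os.chdir(nb_dir)
    sys.path.insert(0, nb_dir)
    sys.dont_write_bytecode = True

    cells = nb.get("cells", [])
    trace = {
        "completed": False, "timed_out": False, "kernel_start_failed": False,
        "cells_executed": 0, "first_exception_type": None,
        "first_exception_value": None, "first_exception_cell": None,
    }
    glb = {"__name__": "__main__"}
    started = time.time()
    signal.signal(signal.SIGALRM, _on_alarm)
    signal.alarm(max(1, int(timeout)))

    count = 0
    code_index = -1
    stop = False
    for cell in cells:
        if cell.get("cell_type") != "code":
            continue
        code_index += 1
        if stop:
            cell["outputs"] = []
            cell["execution_count"] = None
            continue
        count += 1
        trace["cells_executed"] = count
        buf_out, buf_err = io.StringIO(), io.StringIO()
        err_output = None
        try:
            code = compile(_strip_directives(_source(cell)),
                           "<cell %d>" % code_index, "exec")
            with contextlib.redirect_stdout(buf_out), \
                 contextlib.redirect_stderr(buf_err):
                exec(code, glb)
        except _NotebookTimeout:
            trace["timed_out"] = True
            stop = True
        except BaseException as exc:  # noqa: BLE001 - ename must be recorded
            trace["first_exception_type"] = type(exc).__name__
            trace["first_exception_value"] = str(exc)
            trace["first_exception_cell"] = code_index
            err_output = {
                "output_type": "error",
                "ename": type(exc).__name__,
                "evalue": str(exc),
                "traceback": traceback.format_exc().split("\n"),
            }
            stop = True
        outputs = []
        if buf_out.getvalue():
            outputs.append({"output_type": "stream", "name": "stdout",
                            "text": buf_out.getvalue()})
        if buf_err.getvalue():
            outputs.append({"output_type": "stream", "name": "stderr",
                            "text": buf_err.getvalue()})
        if err_output is not None:
            outputs.append(err_output)
        cell["outputs"] = outputs
        cell["execution_count"] = count
        if trace["timed_out"]:
            cell["outputs"] = []
            cell["execution_count"] = None

    signal.alarm(0)
    trace["completed"] = not stop
    trace["duration"] = time.time() - started

    with open(out_nb, "w", encoding="utf-8") as fh:
        json.dump(nb, fh, indent=1)
    with open(out_trace, "w", encoding="utf-8") as fh:
        json.dump(trace, fh)


if __name__ == "__main__":
    main()
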