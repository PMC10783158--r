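"""Parse notebook code cells with the ast module and report imports.

Reads JSON {"cells": ["src", ...]} on stdin; writes JSON list with one entry
per cell: {"ok": bool, "imports": [{"module": str, "level": int}, ...],
"functions": int, "classes": int}. Uses only the standard library.
"""
import ast
import json
import sys


def analyze(src):
    try:
        tree = ast.parse(src)
    except SyntaxError:
        return {"ok": False, "imports": [], "functions": 0, "classes": 0}
    imports = []
    functions = 0
    classes = 0
    for node in ast.walk(tree):
        if isinstance(node, ast.Import):
            for alias in node.names:
                imports.append({"module": alias.name, "level": 0})
        elif isinstance(node, ast.ImportFrom):
            imports.append({"module": node.module or "", "level": node.level})
        elif isinstance(node, (ast.FunctionDef, ast.AsyncFunctionDef)):
            functions += 1
        elif isinstance(node, ast.ClassDef):
            classes += 1
    return {"ok": True, "imports": imports,
            "functions": functions, "classes": classes}


def main():
    payload = json.load(sys.stdin)
    out = [analyze(src) for src in payload.get("cells", [])]
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
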