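"""Batched LP/MILP solving service for the pessknock R package.

Reads a JSON file describing a list of linear or mixed-integer programs,
solves each with HiGHS via scipy.optimize.milp, and writes a JSON file with
one result object per problem.  Batching matters: the R side pays the Python
start-up cost once per call, so callers group independent problems.

Problem schema (all arrays are plain JSON lists):
  sense        : "max" or "min"
  n            : number of variables
  obj          : length-n objective coefficients
  lb, ub       : length-n variable bounds (strings "inf"/"-inf" allowed)
  integer      : length-n 0/1 flags
  ai, aj, ax   : constraint triplets, 1-based row/column indices
  clb, cub     : per-row constraint bounds (lb == ub encodes an equality)
  mip_gap      : optional relative MIP gap
  time_limit   : optional seconds

Result schema: {status, objective, x}
  status in {"optimal", "infeasible", "unbounded", "time_limit", "error"}
"""

import json
import sys

import numpy as np
import scipy.sparse as sp
from scipy.optimize import Bounds, LinearConstraint, milp

_STATUS = {
    0: "optimal",
    1: "time_limit",
    2: "infeasible",
    3: "unbounded",
    4: "error",
}


def _num(v):
    if isinstance(v, str):
        if v == "inf":
            return np.inf
        if v == "-inf":
            return -np.inf
    return float(v)


def _vec(xs):
    return np.array([_num(v) for v in xs], dtype=float)


def solve_one(prob):
    n = int(prob["n"])
    obj = _vec(prob["obj"])
    sense = prob.get("sense", "min")
    c = -obj if sense == "max" else obj

    lb = _vec(prob["lb"])
    ub = _vec(prob["ub"])
    integrality = np.array(prob.get("integer", [0] * n), dtype=int)

    constraints = []
    if prob.get("ai"):
        ai = np.asarray(prob["ai"], dtype=int) - 1
        aj = np.asarray(prob["aj"], dtype=int) - 1
        ax = _vec(prob["ax"])
        m = int(max(ai)) + 1
        A = sp.csr_matrix((ax, (ai, aj)), shape=(m, n))
        constraints.append(LinearConstraint(A, _vec(prob["clb"]), _vec(prob["cub"])))

    options = {}
    if prob.get("mip_gap") is not None:
        options["mip_rel_gap"] = float(prob["mip_gap"])
    if prob.get("time_limit") is not None:
        options["time_limit"] = float(prob["time_limit"])

    try:
        res = milp(
            c,
            constraints=constraints,
            bounds=Bounds(lb, ub),
            integrality=integrality,
            options=options,
        )
    except Exception as exc:  # malformed problem: report, do not kill the batch
        return {"status": "error", "message": str(exc), "objective": None, "x": None}

    status = _STATUS.get(res.status, "error")
    out = {"status": status, "objective": None, "x": None}
    if res.x is not None:
        x = np.asarray(res.x, dtype=float)
        # snap binaries: HiGHS returns values within integrality tolerance
        x[integrality == 1] = np.round(x[integrality == 1])
        out["x"] = x.tolist()
        val = float(obj @ x)
        out["objective"] = val
    return out


def main(argv):
    if len(argv) != 3:
        sys.stderr.write("usage: milp_backend.py <in.json> <out.json>\n")
        return 2
    with open(argv[1]) as fh:
        problems = json.load(fh)
    results = [solve_one(p) for p in problems]
    with open(argv[2], "w") as fh:
        json.dump(results, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
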