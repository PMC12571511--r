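"""Mixed-integer linear program bridge.

Reads a model description (JSON) from argv[1], solves it with HiGHS through
scipy.optimize.milp, and writes the result (JSON) to argv[2].

Model JSON schema:
  nvar         number of decision variables
  obj          objective coefficients (length nvar), minimized
  lb, ub       variable bounds (length nvar); "inf"/-"inf" allowed as 1e30
  integrality  0 = continuous, 1 = integer (length nvar)
  con_i, con_j, con_x   sparse constraint-matrix triplets (1-based rows/cols)
  row_lb, row_ub        constraint row bounds
  time_limit   seconds (optional)
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF = 1e30


def main():
    with open(sys.argv[1]) as fh:
        spec = json.load(fh)

    def arr(key, dtype):
        # length-1 vectors arrive as JSON scalars; missing/empty as []
        v = spec.get(key)
        if v is None:
            v = []
        return np.atleast_1d(np.asarray(v, dtype=dtype))

    nvar = int(spec["nvar"])
    c = arr("obj", float)
    lb = arr("lb", float)
    ub = arr("ub", float)
    lb[lb <= -INF] = -np.inf
    ub[ub >= INF] = np.inf
    integrality = arr("integrality", int)

    ncon = len(arr("row_lb", float))
    constraints = []
    if ncon:
        i = arr("con_i", int) - 1
        j = arr("con_j", int) - 1
        x = arr("con_x", float)
        A = sparse.csc_matrix((x, (i, j)), shape=(ncon, nvar))
        rlb = arr("row_lb", float)
        rub = arr("row_ub", float)
        rlb[rlb <= -INF] = -np.inf
        rub[rub >= INF] = np.inf
        constraints = [LinearConstraint(A, rlb, rub)]

    options = {"presolve": True, "mip_rel_gap": 0.0}
    if spec.get("time_limit") is not None:
        options["time_limit"] = float(spec["time_limit"])

    res = milp(
        c,
        constraints=constraints,
        integrality=integrality,
        bounds=Bounds(lb, ub),
        options=options,
    )

    out = {
        "status": int(res.status),
        "success": bool(res.success),
        "message": str(res.message),
        "objective": None if res.fun is None else float(res.fun),
        "x": None if res.x is None else [float(v) for v in res.x],
        "mip_gap": None if getattr(res, "mip_gap", None) is None else float(res.mip_gap),
    }
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
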