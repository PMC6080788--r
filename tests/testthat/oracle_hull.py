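"""Brute-force LP oracle for 3-D convex hulls.

Reads a JSON file {"clouds": [[[x,y,z],...], ...]} and writes, per cloud,
the hull vertex indices and hull edge index pairs (1-based), each decided by
an independent linear program (HiGHS):

  vertex test: point i is a vertex iff it is not expressible as a convex
  combination of the remaining points (phase-1 feasibility LP).

  edge test: segment (i, j) is a hull edge iff some hyperplane supports the
  hull exactly along it, i.e. max t s.t. w.p_i = b, w.p_j = b,
  w.q <= b - t for all other points q, |w| bounded, attains t > 0.

No convex-hull library is used anywhere in this oracle.
"""

import json
import sys

import numpy as np
from scipy.optimize import linprog


def is_vertex(P, i):
    Q = np.delete(P, i, axis=0)
    n = Q.shape[0]
    A_eq = np.vstack([Q.T, np.ones(n)])
    b_eq = np.append(P[i], 1.0)
    res = linprog(np.zeros(n), A_eq=A_eq, b_eq=b_eq, bounds=(0, None),
                  method="highs")
    return not res.success


def is_edge(P, i, j, tol=1e-9):
    Q = np.delete(P, [i, j], axis=0)
    m = Q.shape[0]
    c = np.zeros(5)
    c[4] = -1.0  # maximize t
    A_ub = np.hstack([Q, -np.ones((m, 1)), np.ones((m, 1))])
    b_ub = np.zeros(m)
    A_eq = np.array([np.append(P[i], [-1.0, 0.0]),
                     np.append(P[j], [-1.0, 0.0])])
    b_eq = np.zeros(2)
    bounds = [(-1, 1)] * 3 + [(None, None), (0, None)]
    res = linprog(c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq,
                  bounds=bounds, method="highs")
    return bool(res.success and -res.fun > tol)


def main(in_path, out_path):
    with open(in_path) as fh:
        data = json.load(fh)
    out = []
    for cloud in data["clouds"]:
        P = np.asarray(cloud, dtype=float)
        n = P.shape[0]
        verts = [i for i in range(n) if is_vertex(P, i)]
        edges = []
        for a in range(len(verts)):
            for b in range(a + 1, len(verts)):
                if is_edge(P, verts[a], verts[b]):
                    edges.append([verts[a] + 1, verts[b] + 1])
        out.append({"vertices": [v + 1 for v in verts], "edges": edges})
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
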