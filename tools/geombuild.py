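"""Geometry kit for constructing the 123-solid reference library.

All solids are built from first principles (exact constructions where simple,
numerical regular-face refinement where not) and verified: every vertex must be
an extreme point of its own convex hull, every face planar and regular to
~1e-12 of the unit edge, and Euler's relation must hold.

Conventions: solids are centred at the vertex centroid and scaled to unit edge
(unit *mean* edge for the Catalan family, whose faces are not regular).
"""

import numpy as np
from scipy.spatial import ConvexHull
from scipy.optimize import least_squares

PHI = (1 + np.sqrt(5)) / 2

# ---------------------------------------------------------------- hull faces

def hull_faces(V, angtol=1e-6, offtol=1e-8, require_extreme=True):
    """Faces of the convex hull of V as merged coplanar polygons.

    Returns (faces, edges): faces are lists of vertex indices in cyclic order
    (counter-clockwise seen from outside), edges a sorted array of index pairs.
    By default requires every point of V to be a hull vertex.
    """
    V = np.asarray(V, float)
    hull = ConvexHull(V)
    if require_extreme and len(hull.vertices) != len(V):
        missing = sorted(set(range(len(V))) - set(hull.vertices))
        raise ValueError(f"{len(missing)} interior/duplicate points, e.g. {missing[:4]}")
    # group triangular simplices by supporting plane
    eqs = hull.equations  # (n, x) . eq[:3] + eq[3] <= 0
    used = np.zeros(len(hull.simplices), bool)
    groups = []
    for i in range(len(hull.simplices)):
        if used[i]:
            continue
        n_i, d_i = eqs[i, :3], eqs[i, 3]
        sel = [i]
        used[i] = True
        for j in range(i + 1, len(hull.simplices)):
            if used[j]:
                continue
            n_j, d_j = eqs[j, :3], eqs[j, 3]
            if np.arccos(np.clip(n_i @ n_j, -1, 1)) < angtol and abs(d_i - d_j) < offtol:
                used[j] = True
                sel.append(j)
        groups.append(sel)
    faces = []
    for sel in groups:
        idx = np.unique(hull.simplices[sel])
        n = eqs[sel[0], :3]
        c = V[idx].mean(axis=0)
        # order CCW around the outward normal
        a = V[idx[0]] - c
        a -= (a @ n) * n
        a /= np.linalg.norm(a)
        b = np.cross(n, a)
        ang = np.arctan2((V[idx] - c) @ b, (V[idx] - c) @ a)
        faces.append(list(idx[np.argsort(ang)]))
    edges = set()
    for f in faces:
        for k in range(len(f)):
            e = (f[k], f[(k + 1) % len(f)])
            edges.add((min(e), max(e)))
    return faces, np.array(sorted(edges), int)


# ------------------------------------------------------------ regular polish

def chord(k, j):
    """Distance between vertices j apart on a regular k-gon with unit edge."""
    return np.sin(j * np.pi / k) / np.sin(np.pi / k)


def polish(V, faces=None, maxiter=200):
    """Refine coordinates so every face is a regular unit-edge polygon.

    Residuals are all intra-face pairwise distances minus the regular-polygon
    chords; a full distance matrix per face forces each face to be congruent to
    the regular k-gon (hence planar).  Topology is taken from the convex hull
    of the input and must survive polishing.
    """
    V = np.asarray(V, float).copy()
    if faces is None:
        faces, _ = hull_faces(V)
    pairs, targets = [], []
    for f in faces:
        k = len(f)
        for a in range(k):
            for b in range(a + 1, k):
                pairs.append((f[a], f[b]))
                targets.append(chord(k, min(b - a, k - (b - a))))
    ii = np.array([p[0] for p in pairs])
    jj = np.array([p[1] for p in pairs])
    tt = np.array(targets)

    def resid(x):
        P = x.reshape(-1, 3)
        d = np.linalg.norm(P[ii] - P[jj], axis=1)
        return d - tt

    # pre-scale to unit mean edge so the initial guess is commensurate
    d0 = np.linalg.norm(V[ii] - V[jj], axis=1)
    V *= np.mean(tt) / np.mean(d0)
    sol = least_squares(resid, V.ravel(), method="trf", xtol=1e-15, ftol=1e-15,
                        gtol=1e-15, max_nfev=maxiter * 3)
    P = sol.x.reshape(-1, 3)
    P -= P.mean(axis=0)
    return P, np.max(np.abs(resid(sol.x)))


# ----------------------------------------------------------------- verifiers

def solid_stats(V, require_regular=True):
    """Validate a finished solid; return summary dict."""
    V = np.asarray(V, float)
    faces, edges = hull_faces(V)
    nv, ne, nf = len(V), len(edges), len(faces)
    assert nv - ne + nf == 2, f"Euler fails: {nv}-{ne}+{nf}"
    el = np.linalg.norm(V[edges[:, 0]] - V[edges[:, 1]], axis=1)
    worst = 0.0
    if require_regular:
        for f in faces:
            k = len(f)
            P = V[f]
            for a in range(k):
                for b in range(a + 1, k):
                    d = np.linalg.norm(P[a] - P[b])
                    worst = max(worst, abs(d - chord(k, min(b - a, k - (b - a)))))
        assert worst < 1e-9, f"faces not regular: {worst}"
    fh = {}
    for f in faces:
        fh[len(f)] = fh.get(len(f), 0) + 1
    deg = np.zeros(nv, int)
    for a, b in edges:
        deg[a] += 1
        deg[b] += 1
    dh = {}
    for d in deg:
        dh[int(d)] = dh.get(int(d), 0) + 1
    return dict(V=nv, E=ne, F=nf, face_hist=dict(sorted(fh.items())),
                degree_hist=dict(sorted(dh.items())),
                edge_min=float(el.min()), edge_max=float(el.max()),
                regular_err=float(worst))


def finish(V, regular=True):
    """Centre at vertex centroid, scale to unit (mean) edge."""
    V = np.asarray(V, float)
    _, edges = hull_faces(V)
    el = np.linalg.norm(V[edges[:, 0]] - V[edges[:, 1]], axis=1)
    V = V / el.mean()
    V = V - V.mean(axis=0)
    return V


# ----------------------------------------------------------- primitive seeds

def ngon(n, z=0.0, phase=0.0, R=None):
    if R is None:
        R = 0.5 / np.sin(np.pi / n)
    a = 2 * np.pi * np.arange(n) / n + phase
    return np.column_stack([R * np.cos(a), R * np.sin(a), np.full(n, z)])


def platonic():
    tet = np.array([[1, 1, 1], [1, -1, -1], [-1, 1, -1], [-1, -1, 1]], float)
    cube = np.array([[x, y, z] for x in (-1, 1) for y in (-1, 1) for z in (-1, 1)], float)
    octa = np.array([[1, 0, 0], [-1, 0, 0], [0, 1, 0], [0, -1, 0], [0, 0, 1], [0, 0, -1]], float)
    b = 1 / PHI
    dod = [[x, y, z] for x in (-1, 1) for y in (-1, 1) for z in (-1, 1)]
    for (p, q) in [(0.0, b)]:
        pass
    cyc = lambda pts: [list(np.roll(p, k)) for p in pts for k in range(3)]
    dod += cyc([[0, s1 * b, s2 * PHI] for s1 in (-1, 1) for s2 in (-1, 1)])
    ico = cyc([[0, s1 * 1.0, s2 * PHI] for s1 in (-1, 1) for s2 in (-1, 1)])
    return dict(tetrahedron=tet, cube=cube, octahedron=octa,
                dodecahedron=np.array(dod, float), icosahedron=np.array(ico, float))


# ------------------------------------------------- vertex-truncation builder

def truncate_vertices(V):
    """Uniformly truncate every vertex of a regular-ish solid.

    The cut ratio t makes the corner polygon edge equal to the shortened
    original edge when the vertex figure is regular; irregular vertex figures
    (icosidodecahedron) give near-regular output for later polishing.
    """
    V = np.asarray(V, float)
    faces, edges = hull_faces(V)
    adj = [[] for _ in range(len(V))]
    for a, b in edges:
        adj[a].append(b)
        adj[b].append(a)
    L = np.linalg.norm(V[edges[0, 0]] - V[edges[0, 1]])
    # mean consecutive-neighbour distance around a vertex
    cs = []
    for v in range(len(V)):
        nb = np.array(adj[v])
        rel = V[nb] - V[v]
        n = rel.mean(axis=0)
        n /= np.linalg.norm(n)
        a0 = rel[0] - (rel[0] @ n) * n
        a0 /= np.linalg.norm(a0)
        b0 = np.cross(n, a0)
        order = nb[np.argsort(np.arctan2(rel @ b0, rel @ a0))]
        for k in range(len(order)):
            cs.append(np.linalg.norm(V[order[k]] - V[order[(k + 1) % len(order)]]))
    c = float(np.mean(cs))
    t = L / (c + 2 * L)
    out = []
    for v in range(len(V)):
        for w in adj[v]:
            out.append(V[v] + t * (V[w] - V[v]))
    return np.array(out)


def rectify(V):
    """Edge midpoints (cuboctahedron / icosidodecahedron from cube / icosa)."""
    _, edges = hull_faces(np.asarray(V, float))
    V = np.asarray(V, float)
    return (V[edges[:, 0]] + V[edges[:, 1]]) / 2


def dual_catalan(V):
    """Polar reciprocal about the midsphere: Catalan from Archimedean."""
    V = np.asarray(V, float)
    V = V - V.mean(axis=0)
    faces, edges = hull_faces(V)
    mid = (V[edges[:, 0]] + V[edges[:, 1]]) / 2
    r2 = np.linalg.norm(mid, axis=1) ** 2
    assert np.ptp(r2) / r2.mean() < 1e-9, "no midsphere — not canonical"
    rho2 = r2.mean()
    out = []
    for f in faces:
        c = V[f].mean(axis=0)
        n = np.cross(V[f[1]] - V[f[0]], V[f[2]] - V[f[0]])
        n /= np.linalg.norm(n)
        if n @ c < 0:
            n = -n
        h = n @ V[f[0]]
        out.append(n * rho2 / h)
    return np.array(out)


def snubify(V, alpha0=0.35, k0=None):
    """Snub operation: shrink each face to unit edge, twist by alpha, push to
    radius k; solve (k, alpha) so all 'short' inter-face distances are 1."""
    V = np.asarray(V, float)
    V = V - V.mean(axis=0)
    faces, _ = hull_faces(V)
    m = len(faces[0])
    base = []
    for f in faces:
        c = V[f].mean(axis=0)
        n = c / np.linalg.norm(c)
        s = 1.0 / np.linalg.norm(V[f[1]] - V[f[0]])
        base.append((c, n, [s * (V[i] - c) for i in f]))
    if k0 is None:
        k0 = np.linalg.norm(base[0][0]) / np.linalg.norm(V[faces[0][0]] - base[0][0]) * 1.2

    def build(k, alpha):
        pts = []
        for c, n, rel in base:
            ca, sa = np.cos(alpha), np.sin(alpha)
            for r in rel:
                rot = r * ca + np.cross(n, r) * sa + n * (n @ r) * (1 - ca)
                pts.append(n * k * np.linalg.norm(c) / np.linalg.norm(base[0][0]) + rot)
        return np.array(pts)

    deg = {3: 5, 4: 5, 5: 5}  # snub solids are 5-regular

    def resid(x):
        P = build(x[0], x[1])
        from scipy.spatial import cKDTree
        t = cKDTree(P)
        d, _ = t.query(P, k=6)
        return (d[:, 1:6] - 1.0).ravel()

    sol = least_squares(resid, np.array([k0, alpha0]), method="lm")
    return build(*sol.x)
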