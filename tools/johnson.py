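"""Construction kit for the 92 Johnson solids (unit edge).

Most Johnson solids are axial stacks of caps (pyramid / cupola / rotunda /
roof) over prism or antiprism bands, or modifications (augment / diminish /
gyrate) of Platonic and Archimedean seeds.  The remaining 'elementary' solids
are obtained by symmetry-constrained least-squares on their edge lengths.
"""

import numpy as np
from scipy.optimize import least_squares
import geombuild as G

PHI = G.PHI


def Rn(n):
    return 0.5 / np.sin(np.pi / n)


def ring(n, R, z, phase):
    a = 2 * np.pi * np.arange(n) / n + phase
    return np.column_stack([R * np.cos(a), R * np.sin(a), np.full(n, z)])


# ---------------------------------------------------------------- caps
# A cap is (interior_points, ring_size); the ring itself (regular ring_size-gon
# of unit edge at z=0, phase 0) is supplied by the assembler.  Interior points
# are given for a cap sitting ABOVE its ring, apex pointing +z.

def cap_polygon(n):
    return np.zeros((0, 3)), n


def cap_pyramid(n):
    h = np.sqrt(1 - Rn(n) ** 2)
    return np.array([[0, 0, h]]), n


def cap_cupola(n):
    # ring is the 2n-gon; apex n-gon between ring vertices 0 and 1
    r2, r1 = Rn(2 * n), Rn(n)
    ph = np.pi / (2 * n)
    h2 = 1 - (r2 ** 2 + r1 ** 2 - 2 * r1 * r2 * np.cos(ph))
    top = ring(n, r1, np.sqrt(h2), ph)
    return top, 2 * n


def cap_rotunda():
    # half icosidodecahedron above an equatorial decagon
    ico = G.platonic()['icosahedron']
    ido = G.finish(G.rectify(ico))
    axis = np.array([0.0, 1.0, PHI])
    axis /= np.linalg.norm(axis)
    t = ido @ axis
    keep = t > -1e-9
    pts = ido[keep]
    # rotate axis -> z
    v = np.cross(axis, [0, 0, 1.0])
    s, c = np.linalg.norm(v), axis @ [0, 0, 1.0]
    K = np.array([[0, -v[2], v[1]], [v[2], 0, -v[0]], [-v[1], v[0], 0]])
    R = np.eye(3) + K + K @ K * ((1 - c) / s ** 2)
    pts = pts @ R.T
    eq = np.abs(pts[:, 2]) < 1e-9
    # phase so that one equator vertex sits at angle 0
    a0 = np.arctan2(pts[eq][0, 1], pts[eq][0, 0])
    ca, sa = np.cos(-a0), np.sin(-a0)
    Rz = np.array([[ca, -sa, 0], [sa, ca, 0], [0, 0, 1]])
    pts = pts @ Rz.T
    interior = pts[~eq]
    return interior, 10


def cap_roof(_n=4):
    # fastigium: unit-square ring, ridge edge parallel to x at height sqrt(3)/2
    h = np.sqrt(3) / 2
    return np.array([[0.5, 0, h], [-0.5, 0, h]]), 4


CAPS = dict(polygon=cap_polygon, pyramid=cap_pyramid, cupola=cap_cupola,
            rotunda=cap_rotunda, roof=cap_roof)


def cap_points(kind, n=None):
    if kind == 'rotunda':
        return cap_rotunda()
    if kind == 'roof':
        ph = np.pi / 4  # ring square with vertices at (+-1/2, +-1/2)
        pts, m = cap_roof()
        return pts, m, ph
    return CAPS[kind](n)


def _rz(pts, ang):
    ca, sa = np.cos(ang), np.sin(ang)
    R = np.array([[ca, -sa, 0], [sa, ca, 0], [0, 0, 1]])
    return pts @ R.T


def stack(top, band=None, bottom=None, gyro=False, n=None):
    """Assemble an axial solid.

    top / bottom: (kind, n) tuples; band: None, 'prism' or 'antiprism' over the
    interface ring; gyro rotates the bottom cap by one ring step.  The
    interface ring size is taken from the top cap.
    """
    kind_t, n_t = top
    if kind_t == 'roof':
        int_t, m, ph_t = cap_points('roof')
    else:
        int_t, m = cap_points(kind_t, n_t)
        ph_t = 0.0
    Rm = Rn(m)
    pts = [ring(m, Rm, 0.0, ph_t), int_t]
    z_b, ph_b = 0.0, ph_t
    if band == 'prism':
        z_b, ph_b = -1.0, ph_t
        pts.append(ring(m, Rm, z_b, ph_b))
    elif band == 'antiprism':
        h2 = 1 - Rm ** 2 * 2 * (1 - np.cos(np.pi / m))
        z_b, ph_b = -np.sqrt(h2), ph_t + np.pi / m
        pts.append(ring(m, Rm, z_b, ph_b))
    if bottom is not None:
        kind_b, n_b = bottom
        if kind_b == 'roof':
            int_b, _, ph_cb = cap_points('roof')
        else:
            int_b, _ = cap_points(kind_b, n_b)
            ph_cb = 0.0
        int_b = int_b.copy()
        int_b[:, 2] = -int_b[:, 2]          # mirror below its ring
        int_b[:, 2] += z_b
        # caps are built for a phase ph_cb ring; re-phase to the bottom ring,
        # plus one full ring step (2*pi/m) for the gyro variant
        int_b = _rz(int_b, (ph_b - ph_cb) + (2 * np.pi / m if gyro else 0.0))
        pts.append(int_b)
    V = np.vstack([p for p in pts if len(p)])
    return V


# ------------------------------------------------------------- glue / modify

def faces_of(V):
    return G.hull_faces(V)[0]


def find_faces(V, size):
    return [f for f in faces_of(V) if len(f) == size]


def attach(V, face, kind, n=None, offset=0):
    """Glue a cap (standard position) onto `face` of solid V (outward)."""
    V = np.asarray(V, float)
    m = len(face)
    if kind == 'roof':
        interior, _, ph = cap_points('roof')
        std_ring = ring(4, Rn(4), 0.0, ph)
    else:
        interior, m2 = cap_points(kind, n)
        assert m2 == m, (kind, n, m, m2)
        std_ring = ring(m, Rn(m), 0.0, 0.0)
    tgt = V[np.array(face)]
    tgt_c = tgt.mean(axis=0)
    # outward normal of the face
    nrm = np.zeros(3)
    for k in range(m):
        nrm += np.cross(tgt[k] - tgt_c, tgt[(k + 1) % m] - tgt_c)
    nrm /= np.linalg.norm(nrm)
    if nrm @ (tgt_c - V.mean(axis=0)) < 0:
        nrm = -nrm
        tgt = tgt[::-1]
    src = std_ring - std_ring.mean(axis=0)
    dst = np.roll(tgt, -offset, axis=0) - tgt_c
    # Kabsch proper rotation src -> dst
    H = src.T @ dst
    U, S, Vt = np.linalg.svd(H)
    d = np.sign(np.linalg.det(Vt.T @ U.T))
    R = Vt.T @ np.diag([1, 1, d]) @ U.T
    out = interior @ R.T + tgt_c
    return np.vstack([V, out])


def diminish(V, idx):
    keep = np.ones(len(V), bool)
    keep[list(idx)] = False
    return V[keep]


def gyrate_cap(V, penta_face):
    """Rotate the 5 apex vertices of a pentagonal-cupola cap by 36 deg."""
    V = np.asarray(V, float).copy()
    c = V[np.array(penta_face)].mean(axis=0)
    axis = c - V.mean(axis=0)
    axis /= np.linalg.norm(axis)
    ang = np.pi / 5
    K = np.array([[0, -axis[2], axis[1]], [axis[2], 0, -axis[0]],
                  [-axis[1], axis[0], 0]])
    R = np.eye(3) + np.sin(ang) * K + (1 - np.cos(ang)) * K @ K
    cen = V.mean(axis=0)
    V[np.array(penta_face)] = (V[np.array(penta_face)] - cen) @ R.T + cen
    return V


# ----------------------------------------------- site selection on a seed

def face_relation(V, f1, f2):
    """'adjacent' (share vertices), 'para' (antipodal centroids) or 'meta'."""
    if set(f1) & set(f2):
        return 'adjacent'
    cen = np.asarray(V, float).mean(axis=0)
    c1 = V[np.array(f1)].mean(axis=0) - cen
    c2 = V[np.array(f2)].mean(axis=0) - cen
    c1 = c1 / np.linalg.norm(c1)
    c2 = c2 / np.linalg.norm(c2)
    if c1 @ c2 < -1 + 1e-6:
        return 'para'
    return 'meta'


def pick_sites(V, faces, rels):
    """Pick len(rels)+1 faces with pairwise relations as requested.

    rels: list like ['para'] or ['meta','meta'] giving the relation of each
    subsequent face to ALL previously chosen ones.
    """
    import itertools
    for combo in itertools.combinations(range(len(faces)), len(rels) + 1):
        ok = True
        for i in range(1, len(combo)):
            for j in range(i):
                want = rels[i - 1]
                if face_relation(V, faces[combo[j]], faces[combo[i]]) != want:
                    ok = False
                    break
            if not ok:
                break
        if ok:
            return [faces[k] for k in combo]
    raise ValueError("no site combination found")
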