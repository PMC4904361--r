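"""Generate the 123-solid reference library as packaged text data.

Writes one vertex-coordinate file per solid under inst/extdata/solids/ plus a
manifest.json with per-solid combinatorial summaries.  Every solid is verified
before writing: all vertices extreme on the convex hull, Euler's relation,
face planarity (T = lambda3/lambda2 below 1e-9), regular faces to 1e-9 of the
unit edge (all families except Catalan, whose faces are planar but irregular),
and agreement with the known vertex/edge/face counts.

Run from tools/:  python make_solid_library.py
"""

import json
import os
import numpy as np
import geombuild as G
import johnson as J
import elemsearch as E
from scipy.optimize import least_squares

OUT = os.path.join(os.path.dirname(__file__), "..", "inst", "extdata", "solids")
PHI = G.PHI


# ---------------------------------------------------------------- seeds

def archimedean():
    import itertools
    P = G.platonic()
    sq2 = np.sqrt(2)
    cyc = lambda v: [list(np.roll(v, k)) for k in range(3)]
    A = {}
    A['truncated tetrahedron'] = G.truncate_vertices(P['tetrahedron'])
    A['cuboctahedron'] = G.rectify(P['cube'])
    A['truncated cube'] = G.truncate_vertices(P['cube'])
    A['truncated octahedron'] = G.truncate_vertices(P['octahedron'])
    A['rhombicuboctahedron'] = np.array(
        [np.roll([x, y, z], k) for k in range(3)
         for x in (-1, 1) for y in (-1, 1) for z in (-(1 + sq2), 1 + sq2)])
    pts = []
    for perm in itertools.permutations(range(3)):
        for s in itertools.product((-1, 1), repeat=3):
            base = [1, 1 + sq2, 1 + 2 * sq2]
            pts.append([s[i] * base[perm[i]] for i in range(3)])
    A['truncated cuboctahedron'] = np.unique(np.round(pts, 12), axis=0)
    # snub cube: tribonacci coordinates (one enantiomorph)
    t = (1 + (19 + 3 * np.sqrt(33)) ** (1 / 3) + (19 - 3 * np.sqrt(33)) ** (1 / 3)) / 3
    pts = []
    for perm in itertools.permutations(range(3)):
        par = sum(1 for i in range(3) for j in range(i + 1, 3) if perm[i] > perm[j]) % 2
        for s in itertools.product((-1, 1), repeat=3):
            if (par + sum(1 for x in s if x < 0)) % 2 == 0:
                base = [1, 1 / t, t]
                pts.append([s[i] * base[perm[i]] for i in range(3)])
    A['snub cube'] = np.unique(np.round(pts, 12), axis=0)
    A['icosidodecahedron'] = G.rectify(P['icosahedron'])
    A['truncated dodecahedron'] = G.truncate_vertices(P['dodecahedron'])
    A['truncated icosahedron'] = G.truncate_vertices(P['icosahedron'])
    pts = []
    for x in (-1, 1):
        for y in (-1, 1):
            for z in (-1, 1):
                pts += cyc([x * 1.0, y * 1.0, z * PHI ** 3])
                pts += cyc([x * PHI ** 2, y * PHI, z * 2 * PHI])
    for x in (-1, 1):
        for z in (-1, 1):
            pts += cyc([x * (2 + PHI), 0.0, z * PHI ** 2])
    A['rhombicosidodecahedron'] = np.unique(np.round(pts, 12), axis=0)
    A['truncated icosidodecahedron'] = G.truncate_vertices(A['icosidodecahedron'])
    A['snub dodecahedron'] = G.snubify(G.finish(P['dodecahedron']), alpha0=0.25)
    return A


CATALAN_OF = [
    ('triakis tetrahedron', 'truncated tetrahedron'),
    ('rhombic dodecahedron', 'cuboctahedron'),
    ('triakis octahedron', 'truncated cube'),
    ('tetrakis hexahedron', 'truncated octahedron'),
    ('deltoidal icositetrahedron', 'rhombicuboctahedron'),
    ('disdyakis dodecahedron', 'truncated cuboctahedron'),
    ('pentagonal icositetrahedron', 'snub cube'),
    ('rhombic triacontahedron', 'icosidodecahedron'),
    ('triakis icosahedron', 'truncated dodecahedron'),
    ('pentakis dodecahedron', 'truncated icosahedron'),
    ('deltoidal hexecontahedron', 'rhombicosidodecahedron'),
    ('disdyakis triacontahedron', 'truncated icosidodecahedron'),
    ('pentagonal hexecontahedron', 'snub dodecahedron'),
]


# ------------------------------------------------------------- Johnson

def prism(n):
    return J.stack(('polygon', n), band='prism', bottom=('polygon', n))


def attach_regular(V, face, kind, n):
    """Glue a cap in whichever seating keeps the solid convex with regular,
    unmerged faces."""
    for off in (0, 1):
        try:
            W = J.attach(V, face, kind, n, offset=off)
            G.solid_stats(G.finish(W), require_regular=True)
            return W
        except Exception:
            continue
    raise ValueError("no convex regular seating")


def augment_all(V, faces, kind, n):
    for f in faces:
        V = attach_regular(V, f, kind, n)
    return V


def ico_diminished(which):
    ico = G.finish(G.platonic()['icosahedron'])
    faces, edges = G.hull_faces(ico)
    adj = set(map(tuple, edges))

    def rel(i, j):
        if (min(i, j), max(i, j)) in adj:
            return 'adjacent'
        if np.allclose(ico[i], -ico[j], atol=1e-9):
            return 'para'
        return 'meta'
    import itertools
    if which == 'meta2':
        pick = next((i, j) for i, j in itertools.combinations(range(12), 2)
                    if rel(i, j) == 'meta')
        return J.diminish(ico, list(pick))
    pick = next(c for c in itertools.combinations(range(12), 3)
                if all(rel(a, b) == 'meta' for a, b in itertools.combinations(c, 2)))
    return J.diminish(ico, list(pick))


def j64():
    v = G.finish(ico_diminished('tri'))
    faces, _ = G.hull_faces(v)
    pents = [set(f) for f in faces if len(f) == 5]
    for f in faces:
        if len(f) == 3:
            shared = sum(1 for k in range(3)
                         if any({f[k], f[(k + 1) % 3]} <= p for p in pents))
            if shared == 3:
                return J.attach(v, f, 'pyramid', 3)
    raise ValueError("central triangle not found")


def rid_family(op, rels):
    """gyrate ('g') / diminish ('d') the rhombicosidodecahedron at cap sites
    whose pairwise relations follow `rels` (para/meta), ops applied in order
    given by `op` string, e.g. op='gd' rels=['para']."""
    rid = G.finish(archimedean()['rhombicosidodecahedron'])
    pf = J.find_faces(rid, 5)
    faces_all, _ = G.hull_faces(rid)

    def capset(f):
        s = set(f)
        out = set()
        for g in faces_all:
            if set(g) & s:
                out |= set(g)
        return out

    def rel(f1, f2):
        if capset(f1) & capset(f2):
            return 'adjacent'
        c1 = rid[np.array(f1)].mean(axis=0)
        c2 = rid[np.array(f2)].mean(axis=0)
        return 'para' if np.linalg.norm(c1 + c2) < 1e-6 else 'meta'
    import itertools
    sites = None
    for combo in itertools.combinations(range(len(pf)), len(op)):
        ok = True
        for i in range(1, len(combo)):
            for j in range(i):
                if rel(pf[combo[j]], pf[combo[i]]) != rels[i - 1]:
                    ok = False
                    break
            if not ok:
                break
        if ok:
            sites = [pf[k] for k in combo]
            break
    V = rid
    drop = []
    for o, f in zip(op, sites):
        if o == 'g':
            V = J.gyrate_cap(V, f)
        else:
            drop += list(f)
    if drop:
        V = J.diminish(V, drop)
    return V


# ------------------------------------------------- elementary (J84-J92)

def elementary():
    sols = {}
    # J84 snub disphenoid (D2d template)
    def b84(p):
        t, h, a, b, c = p
        return np.array([(t, 0, h), (-t, 0, h), (0, t, -h), (0, -t, -h),
                         (a, b, c), (-a, -b, c), (b, -a, -c), (-b, a, -c)])
    def s84(rng):
        return [rng.uniform(0.4, 0.7), rng.uniform(0.6, 0.9),
                rng.uniform(0.7, 1.0), rng.uniform(0.0, 0.4), rng.uniform(-0.2, 0.2)]
    sols['J84'] = E.search(b84, s84, {3: 12}, ntrials=200, seed=101)[0]

    # J85 snub square antiprism (D4d template)
    def b85(p):
        R1, h1, R2, th0, z2 = p
        pts = []
        for k in range(4):
            a = np.pi / 2 * k
            pts.append((R1 * np.cos(a), R1 * np.sin(a), h1))
            pts.append((R1 * np.cos(a + np.pi / 4), R1 * np.sin(a + np.pi / 4), -h1))
        for k in range(8):
            a = th0 + np.pi / 4 * k
            pts.append((R2 * np.cos(a), R2 * np.sin(a), z2 * (1 if k % 2 == 0 else -1)))
        return np.array(pts)
    def s85(rng):
        return [rng.uniform(0.6, 0.85), rng.uniform(0.7, 1.0),
                rng.uniform(1.0, 1.3), rng.uniform(0.0, 0.4), rng.uniform(0.1, 0.3)]
    sols['J85'] = E.search(b85, s85, {3: 24, 4: 2}, ntrials=200, seed=102)[0]

    # J86 sphenocorona (C2v: wedge + x pair + y pair)
    def b86(p):
        xB, zB, xD, zD, yE, zE = p
        pts = [(0, .5, 0), (0, -.5, 0)]
        pts += [(sx * xB, sy * .5, zB) for sx in (1, -1) for sy in (1, -1)]
        pts += [(sx * xD, 0, zD) for sx in (1, -1)]
        pts += [(0, sy * yE, zE) for sy in (1, -1)]
        return np.array(pts)
    def s86(rng):
        ang = rng.uniform(0.3, 1.2)
        return [np.cos(ang), -np.sin(ang), rng.uniform(0.4, 1.5),
                rng.uniform(-1.5, -0.4), rng.uniform(0.6, 1.4), rng.uniform(-1.2, -0.2)]
    sols['J86'] = E.search(b86, s86, {3: 12, 4: 2}, ntrials=300, seed=103)[0]

    # J87 augmented sphenocorona
    sq = J.find_faces(sols['J86'], 4)[0]
    sols['J87'] = G.finish(J.attach(sols['J86'], sq, 'pyramid', 4))

    # J88 sphenomegacorona (C2v: wedge + x pair + two y pairs)
    def b88(p):
        xB, zB = p[0], p[1]
        pts = [(0, .5, 0), (0, -.5, 0)]
        pts += [(sx * xB, sy * .5, zB) for sx in (1, -1) for sy in (1, -1)]
        for k, ax in enumerate('xyy'):
            a, z = p[2 + 2 * k], p[3 + 2 * k]
            if ax == 'x':
                pts += [(s * a, 0, z) for s in (1, -1)]
            else:
                pts += [(0, s * a, z) for s in (1, -1)]
        return np.array(pts)
    def s88(rng):
        ang = rng.uniform(0.2, 1.4)
        out = [np.cos(ang), -np.sin(ang)]
        for k in range(3):
            out += [rng.uniform(0.3, 1.8), rng.uniform(-1.8, 0.3)]
        return out
    sols['J88'] = E.search(b88, s88, {3: 16, 4: 2}, ntrials=500, seed=104)[0]

    # J89 hebesphenomegacorona (C2v: 3-square blunt wedge + x pair + two y pairs)
    def b89(p):
        yB, zB = p[0], p[1]
        pts = [(sx * .5, sy * .5, 0) for sx in (1, -1) for sy in (1, -1)]
        pts += [(sx * .5, sy * yB, zB) for sx in (1, -1) for sy in (1, -1)]
        for k, ax in enumerate('xyy'):
            a, z = p[2 + 2 * k], p[3 + 2 * k]
            if ax == 'x':
                pts += [(s * a, 0, z) for s in (1, -1)]
            else:
                pts += [(0, s * a, z) for s in (1, -1)]
        return np.array(pts)
    def s89(rng):
        out = [rng.uniform(0.7, 1.5), rng.uniform(-1.2, -0.1)]
        for k in range(3):
            out += [rng.uniform(0.3, 1.9), rng.uniform(-2.0, 0.2)]
        return out
    sols['J89'] = E.search(b89, s89, {3: 18, 4: 3}, ntrials=500, seed=105)[0]

    # J90 disphenocingulum (D2d: two wedges + S4 belt)
    def b90(p):
        zA, xB, zB, xC, yC, zC = p
        pts = [(0, .5, zA), (0, -.5, zA), (.5, 0, -zA), (-.5, 0, -zA)]
        pts += [(sx * xB, sy * .5, zB) for sx in (1, -1) for sy in (1, -1)]
        pts += [(.5 * s, sx * xB, -zB) for s in (1, -1) for sx in (1, -1)]
        x, y, z = xC, yC, zC
        pts += [(x, y, z), (y, -x, -z), (-x, -y, z), (-y, x, -z)]
        return np.array(pts)
    def s90(rng):
        return [rng.uniform(0.5, 1.2), rng.uniform(0.6, 1.3), rng.uniform(0.0, 0.8),
                rng.uniform(0.4, 1.5), rng.uniform(0.0, 1.2), rng.uniform(-0.6, 0.6)]
    sols['J90'] = E.search(b90, s90, {3: 20, 4: 4}, ntrials=500, seed=106)[0]

    # J91 bilunabirotunda: exact golden-ratio coordinates
    pts = [(sx * .5, 0, sz * PHI ** 2 / 2) for sx in (1, -1) for sz in (1, -1)]
    pts += [(sx * PHI / 2, sy * .5, sz * .5)
            for sx in (1, -1) for sy in (1, -1) for sz in (1, -1)]
    pts += [(0, s * PHI / 2, 0) for s in (1, -1)]
    sols['J91'] = G.finish(np.array(pts))

    # J92 triangular hebesphenorotunda: icosidodecahedral cap closed by a
    # unit hexagon (two-parameter solve)
    ido = G.finish(G.rectify(G.platonic()['icosahedron']))
    faces, _ = G.hull_faces(ido)
    tri = [f for f in faces if len(f) == 3][0]
    a = ido[np.array(tri)].mean(axis=0)
    a /= np.linalg.norm(a)
    v = np.cross(a, [0, 0, 1.0])
    s, c = np.linalg.norm(v), a @ [0, 0, 1.0]
    K = np.array([[0, -v[2], v[1]], [v[2], 0, -v[0]], [-v[1], v[0], 0]])
    R = np.eye(3) + K + K @ K * ((1 - c) / s ** 2)
    P = ido @ R.T
    cap = P[P[:, 2] > 0.5]
    ringB = cap[np.abs(cap[:, 2] - 0.934172) < 1e-4]
    ringC = cap[np.abs(cap[:, 2] - 0.577350) < 1e-4]

    def eqs(x):
        zh, dH = x
        ang = dH + 2 * np.pi * np.arange(6) / 6
        hexv = np.column_stack([np.cos(ang), np.sin(ang), np.full(6, zh)])
        dB = np.linalg.norm(hexv[:, None, :] - ringB[None, :, :], axis=2).min()
        dC = np.linalg.norm(hexv[:, None, :] - ringC[None, :, :], axis=2).min()
        return [dB - 1, dC - 1]
    got = None
    for zh0 in (-0.3, -0.1, 0.1):
        for dh0 in np.linspace(0, np.pi / 3, 7):
            sol = least_squares(eqs, [zh0, dh0], method='lm')
            if sol.cost < 1e-20:
                zh, dH = sol.x
                ang = dH + 2 * np.pi * np.arange(6) / 6
                hexv = np.column_stack([np.cos(ang), np.sin(ang), np.full(6, zh)])
                V = G.finish(np.vstack([cap, hexv]))
                try:
                    st = G.solid_stats(V)
                    if st['face_hist'] == {3: 13, 4: 3, 5: 3, 6: 1}:
                        got = V
                        break
                except Exception:
                    continue
        if got is not None:
            break
    sols['J92'] = got
    for k, v in sols.items():
        if v is None:
            raise RuntimeError(f"elementary solid {k} failed to build")
    return sols


def johnson_all():
    S = J.stack
    sols = {}
    sols['J1'] = S(('pyramid', 4))
    sols['J2'] = S(('pyramid', 5))
    sols['J3'] = S(('cupola', 3))
    sols['J4'] = S(('cupola', 4))
    sols['J5'] = S(('cupola', 5))
    sols['J6'] = S(('rotunda', None))
    sols['J7'] = S(('pyramid', 3), band='prism')
    sols['J8'] = S(('pyramid', 4), band='prism')
    sols['J9'] = S(('pyramid', 5), band='prism')
    sols['J10'] = S(('pyramid', 4), band='antiprism')
    sols['J11'] = S(('pyramid', 5), band='antiprism')
    sols['J12'] = S(('pyramid', 3), bottom=('pyramid', 3))
    sols['J13'] = S(('pyramid', 5), bottom=('pyramid', 5))
    sols['J14'] = S(('pyramid', 3), band='prism', bottom=('pyramid', 3))
    sols['J15'] = S(('pyramid', 4), band='prism', bottom=('pyramid', 4))
    sols['J16'] = S(('pyramid', 5), band='prism', bottom=('pyramid', 5))
    sols['J17'] = S(('pyramid', 4), band='antiprism', bottom=('pyramid', 4))
    sols['J18'] = S(('cupola', 3), band='prism')
    sols['J19'] = S(('cupola', 4), band='prism')
    sols['J20'] = S(('cupola', 5), band='prism')
    sols['J21'] = S(('rotunda', None), band='prism')
    sols['J22'] = S(('cupola', 3), band='antiprism')
    sols['J23'] = S(('cupola', 4), band='antiprism')
    sols['J24'] = S(('cupola', 5), band='antiprism')
    sols['J25'] = S(('rotunda', None), band='antiprism')
    sols['J26'] = S(('roof', None), bottom=('roof', None), gyro=True)
    sols['J27'] = S(('cupola', 3), bottom=('cupola', 3))
    sols['J28'] = S(('cupola', 4), bottom=('cupola', 4))
    sols['J29'] = S(('cupola', 4), bottom=('cupola', 4), gyro=True)
    sols['J30'] = S(('cupola', 5), bottom=('cupola', 5))
    sols['J31'] = S(('cupola', 5), bottom=('cupola', 5), gyro=True)
    sols['J32'] = S(('cupola', 5), bottom=('rotunda', None))
    sols['J33'] = S(('cupola', 5), bottom=('rotunda', None), gyro=True)
    sols['J34'] = S(('rotunda', None), bottom=('rotunda', None))
    sols['J35'] = S(('cupola', 3), band='prism', bottom=('cupola', 3))
    sols['J36'] = S(('cupola', 3), band='prism', bottom=('cupola', 3), gyro=True)
    sols['J37'] = S(('cupola', 4), band='prism', bottom=('cupola', 4), gyro=True)
    sols['J38'] = S(('cupola', 5), band='prism', bottom=('cupola', 5))
    sols['J39'] = S(('cupola', 5), band='prism', bottom=('cupola', 5), gyro=True)
    sols['J40'] = S(('cupola', 5), band='prism', bottom=('rotunda', None))
    sols['J41'] = S(('cupola', 5), band='prism', bottom=('rotunda', None), gyro=True)
    sols['J42'] = S(('rotunda', None), band='prism', bottom=('rotunda', None))
    sols['J43'] = S(('rotunda', None), band='prism', bottom=('rotunda', None), gyro=True)
    sols['J44'] = S(('cupola', 3), band='antiprism', bottom=('cupola', 3))
    sols['J45'] = S(('cupola', 4), band='antiprism', bottom=('cupola', 4))
    sols['J46'] = S(('cupola', 5), band='antiprism', bottom=('cupola', 5))
    sols['J47'] = S(('cupola', 5), band='antiprism', bottom=('rotunda', None))
    sols['J48'] = S(('rotunda', None), band='antiprism', bottom=('rotunda', None))

    tp = prism(3)
    sq = J.find_faces(tp, 4)
    sols['J49'] = J.attach(tp, sq[0], 'pyramid', 4)
    sols['J50'] = augment_all(tp, J.pick_sites(tp, sq, ['adjacent']), 'pyramid', 4)
    sols['J51'] = augment_all(tp, sq, 'pyramid', 4)
    pp = prism(5)
    sq = J.find_faces(pp, 4)
    sols['J52'] = J.attach(pp, sq[0], 'pyramid', 4)
    sols['J53'] = augment_all(pp, J.pick_sites(pp, sq, ['meta']), 'pyramid', 4)
    hp = prism(6)
    sq = J.find_faces(hp, 4)
    sols['J54'] = J.attach(hp, sq[0], 'pyramid', 4)
    sols['J55'] = augment_all(hp, J.pick_sites(hp, sq, ['para']), 'pyramid', 4)
    sols['J56'] = augment_all(hp, J.pick_sites(hp, sq, ['meta']), 'pyramid', 4)
    sols['J57'] = augment_all(hp, J.pick_sites(hp, sq, ['meta', 'meta']), 'pyramid', 4)

    dod = G.finish(G.platonic()['dodecahedron'])
    pf = J.find_faces(dod, 5)
    sols['J58'] = J.attach(dod, pf[0], 'pyramid', 5)
    sols['J59'] = augment_all(dod, J.pick_sites(dod, pf, ['para']), 'pyramid', 5)
    sols['J60'] = augment_all(dod, J.pick_sites(dod, pf, ['meta']), 'pyramid', 5)
    sols['J61'] = augment_all(dod, J.pick_sites(dod, pf, ['meta', 'meta']), 'pyramid', 5)

    sols['J62'] = ico_diminished('meta2')
    sols['J63'] = ico_diminished('tri')
    sols['J64'] = j64()

    tt = G.finish(G.truncate_vertices(G.platonic()['tetrahedron']))
    sols['J65'] = attach_regular(tt, J.find_faces(tt, 6)[0], 'cupola', 3)
    tc = G.finish(G.truncate_vertices(G.platonic()['cube']))
    octs = J.find_faces(tc, 8)
    sols['J66'] = attach_regular(tc, octs[0], 'cupola', 4)
    V = tc
    for f in J.pick_sites(tc, octs, ['para']):
        V = attach_regular(V, f, 'cupola', 4)
    sols['J67'] = V
    td = G.finish(G.truncate_vertices(G.platonic()['dodecahedron']))
    decs = J.find_faces(td, 10)
    sols['J68'] = attach_regular(td, decs[0], 'cupola', 5)
    for nm, rels in (('J69', ['para']), ('J70', ['meta']), ('J71', ['meta', 'meta'])):
        V = td
        for f in J.pick_sites(td, decs, rels):
            V = attach_regular(V, f, 'cupola', 5)
        sols[nm] = V

    sols['J72'] = rid_family('g', [])
    sols['J73'] = rid_family('gg', ['para'])
    sols['J74'] = rid_family('gg', ['meta'])
    sols['J75'] = rid_family('ggg', ['meta', 'meta'])
    sols['J76'] = rid_family('d', [])
    sols['J77'] = rid_family('gd', ['para'])
    sols['J78'] = rid_family('gd', ['meta'])
    sols['J79'] = rid_family('ggd', ['meta', 'meta'])
    sols['J80'] = rid_family('dd', ['para'])
    sols['J81'] = rid_family('dd', ['meta'])
    sols['J82'] = rid_family('gdd', ['meta', 'meta'])
    sols['J83'] = rid_family('ddd', ['meta', 'meta'])

    sols.update(elementary())
    return sols


JOHNSON_NAMES = {
    'J1': 'square pyramid', 'J2': 'pentagonal pyramid', 'J3': 'triangular cupola',
    'J4': 'square cupola', 'J5': 'pentagonal cupola', 'J6': 'pentagonal rotunda',
    'J7': 'elongated triangular pyramid', 'J8': 'elongated square pyramid',
    'J9': 'elongated pentagonal pyramid', 'J10': 'gyroelongated square pyramid',
    'J11': 'gyroelongated pentagonal pyramid', 'J12': 'triangular bipyramid',
    'J13': 'pentagonal bipyramid', 'J14': 'elongated triangular bipyramid',
    'J15': 'elongated square bipyramid', 'J16': 'elongated pentagonal bipyramid',
    'J17': 'gyroelongated square bipyramid', 'J18': 'elongated triangular cupola',
    'J19': 'elongated square cupola', 'J20': 'elongated pentagonal cupola',
    'J21': 'elongated pentagonal rotunda', 'J22': 'gyroelongated triangular cupola',
    'J23': 'gyroelongated square cupola', 'J24': 'gyroelongated pentagonal cupola',
    'J25': 'gyroelongated pentagonal rotunda', 'J26': 'gyrobifastigium',
    'J27': 'triangular orthobicupola', 'J28': 'square orthobicupola',
    'J29': 'square gyrobicupola', 'J30': 'pentagonal orthobicupola',
    'J31': 'pentagonal gyrobicupola', 'J32': 'pentagonal orthocupolarotunda',
    'J33': 'pentagonal gyrocupolarotunda', 'J34': 'pentagonal orthobirotunda',
    'J35': 'elongated triangular orthobicupola',
    'J36': 'elongated triangular gyrobicupola', 'J37': 'elongated square gyrobicupola',
    'J38': 'elongated pentagonal orthobicupola',
    'J39': 'elongated pentagonal gyrobicupola',
    'J40': 'elongated pentagonal orthocupolarotunda',
    'J41': 'elongated pentagonal gyrocupolarotunda',
    'J42': 'elongated pentagonal orthobirotunda',
    'J43': 'elongated pentagonal gyrobirotunda',
    'J44': 'gyroelongated triangular bicupola', 'J45': 'gyroelongated square bicupola',
    'J46': 'gyroelongated pentagonal bicupola',
    'J47': 'gyroelongated pentagonal cupolarotunda',
    'J48': 'gyroelongated pentagonal birotunda', 'J49': 'augmented triangular prism',
    'J50': 'biaugmented triangular prism', 'J51': 'triaugmented triangular prism',
    'J52': 'augmented pentagonal prism', 'J53': 'biaugmented pentagonal prism',
    'J54': 'augmented hexagonal prism', 'J55': 'parabiaugmented hexagonal prism',
    'J56': 'metabiaugmented hexagonal prism', 'J57': 'triaugmented hexagonal prism',
    'J58': 'augmented dodecahedron', 'J59': 'parabiaugmented dodecahedron',
    'J60': 'metabiaugmented dodecahedron', 'J61': 'triaugmented dodecahedron',
    'J62': 'metabidiminished icosahedron', 'J63': 'tridiminished icosahedron',
    'J64': 'augmented tridiminished icosahedron',
    'J65': 'augmented truncated tetrahedron', 'J66': 'augmented truncated cube',
    'J67': 'biaugmented truncated cube', 'J68': 'augmented truncated dodecahedron',
    'J69': 'parabiaugmented truncated dodecahedron',
    'J70': 'metabiaugmented truncated dodecahedron',
    'J71': 'triaugmented truncated dodecahedron',
    'J72': 'gyrate rhombicosidodecahedron',
    'J73': 'parabigyrate rhombicosidodecahedron',
    'J74': 'metabigyrate rhombicosidodecahedron',
    'J75': 'trigyrate rhombicosidodecahedron',
    'J76': 'diminished rhombicosidodecahedron',
    'J77': 'paragyrate diminished rhombicosidodecahedron',
    'J78': 'metagyrate diminished rhombicosidodecahedron',
    'J79': 'bigyrate diminished rhombicosidodecahedron',
    'J80': 'parabidiminished rhombicosidodecahedron',
    'J81': 'metabidiminished rhombicosidodecahedron',
    'J82': 'gyrate bidiminished rhombicosidodecahedron',
    'J83': 'tridiminished rhombicosidodecahedron', 'J84': 'snub disphenoid',
    'J85': 'snub square antiprism', 'J86': 'sphenocorona',
    'J87': 'augmented sphenocorona', 'J88': 'sphenomegacorona',
    'J89': 'hebesphenomegacorona', 'J90': 'disphenocingulum',
    'J91': 'bilunabirotunda', 'J92': 'triangular hebesphenorotunda',
}

# known (V, E, F) for every solid, used as an independent check
EXPECTED = {
    'tetrahedron': (4, 6, 4), 'cube': (8, 12, 6), 'octahedron': (6, 12, 8),
    'dodecahedron': (20, 30, 12), 'icosahedron': (12, 30, 20),
    'truncated tetrahedron': (12, 18, 8), 'cuboctahedron': (12, 24, 14),
    'truncated cube': (24, 36, 14), 'truncated octahedron': (24, 36, 14),
    'rhombicuboctahedron': (24, 48, 26), 'truncated cuboctahedron': (48, 72, 26),
    'snub cube': (24, 60, 38), 'icosidodecahedron': (30, 60, 32),
    'truncated dodecahedron': (60, 90, 32), 'truncated icosahedron': (60, 90, 32),
    'rhombicosidodecahedron': (60, 120, 62),
    'truncated icosidodecahedron': (120, 180, 62), 'snub dodecahedron': (60, 150, 92),
    'triakis tetrahedron': (8, 18, 12), 'rhombic dodecahedron': (14, 24, 12),
    'triakis octahedron': (14, 36, 24), 'tetrakis hexahedron': (14, 36, 24),
    'deltoidal icositetrahedron': (26, 48, 24), 'disdyakis dodecahedron': (26, 72, 48),
    'pentagonal icositetrahedron': (38, 60, 24), 'rhombic triacontahedron': (32, 60, 30),
    'triakis icosahedron': (32, 90, 60), 'pentakis dodecahedron': (32, 90, 60),
    'deltoidal hexecontahedron': (62, 120, 60),
    'disdyakis triacontahedron': (62, 180, 120),
    'pentagonal hexecontahedron': (92, 150, 60),
    'J1': (5, 8, 5), 'J2': (6, 10, 6), 'J3': (9, 15, 8), 'J4': (12, 20, 10),
    'J5': (15, 25, 12), 'J6': (20, 35, 17), 'J7': (7, 12, 7), 'J8': (9, 16, 9),
    'J9': (11, 20, 11), 'J10': (9, 20, 13), 'J11': (11, 25, 16), 'J12': (5, 9, 6),
    'J13': (7, 15, 10), 'J14': (8, 15, 9), 'J15': (10, 20, 12), 'J16': (12, 25, 15),
    'J17': (10, 24, 16), 'J18': (15, 27, 14), 'J19': (20, 36, 18),
    'J20': (25, 45, 22), 'J21': (30, 55, 27), 'J22': (15, 33, 20),
    'J23': (20, 44, 26), 'J24': (25, 55, 32), 'J25': (30, 65, 37), 'J26': (8, 14, 8),
    'J27': (12, 24, 14), 'J28': (16, 32, 18), 'J29': (16, 32, 18),
    'J30': (20, 40, 22), 'J31': (20, 40, 22), 'J32': (25, 50, 27),
    'J33': (25, 50, 27), 'J34': (30, 60, 32), 'J35': (18, 36, 20),
    'J36': (18, 36, 20), 'J37': (24, 48, 26), 'J38': (30, 60, 32),
    'J39': (30, 60, 32), 'J40': (35, 70, 37), 'J41': (35, 70, 37),
    'J42': (40, 80, 42), 'J43': (40, 80, 42), 'J44': (18, 42, 26),
    'J45': (24, 56, 34), 'J46': (30, 70, 42), 'J47': (35, 80, 47),
    'J48': (40, 90, 52), 'J49': (7, 13, 8), 'J50': (8, 17, 11), 'J51': (9, 21, 14),
    'J52': (11, 19, 10), 'J53': (12, 23, 13), 'J54': (13, 22, 11),
    'J55': (14, 26, 14), 'J56': (14, 26, 14), 'J57': (15, 30, 17),
    'J58': (21, 35, 16), 'J59': (22, 40, 20), 'J60': (22, 40, 20),
    'J61': (23, 45, 24), 'J62': (10, 20, 12), 'J63': (9, 15, 8), 'J64': (10, 18, 10),
    'J65': (15, 27, 14), 'J66': (28, 48, 22), 'J67': (32, 60, 30),
    'J68': (65, 105, 42), 'J69': (70, 120, 52), 'J70': (70, 120, 52),
    'J71': (75, 135, 62), 'J72': (60, 120, 62), 'J73': (60, 120, 62),
    'J74': (60, 120, 62), 'J75': (60, 120, 62), 'J76': (55, 105, 52),
    'J77': (55, 105, 52), 'J78': (55, 105, 52), 'J79': (55, 105, 52),
    'J80': (50, 90, 42), 'J81': (50, 90, 42), 'J82': (50, 90, 42),
    'J83': (45, 75, 32), 'J84': (8, 18, 12), 'J85': (16, 40, 26),
    'J86': (10, 22, 14), 'J87': (11, 26, 17), 'J88': (12, 28, 18),
    'J89': (14, 33, 21), 'J90': (16, 38, 24), 'J91': (14, 26, 14),
    'J92': (18, 36, 20),
}


def coplanarity_max(V, faces):
    worst = 0.0
    for f in faces:
        P = V[np.array(f)]
        P = P - P.mean(axis=0)
        lam = np.sort(np.linalg.eigvalsh(P.T @ P))[::-1]
        if len(f) > 3:
            worst = max(worst, lam[2] / lam[1])
    return worst


def main():
    os.makedirs(OUT, exist_ok=True)
    entries = []
    sid = 0

    def emit(name, family, V, regular=True):
        nonlocal sid
        sid += 1
        V = G.finish(V)
        faces, edges = G.hull_faces(V)
        if regular:
            V, err = G.polish(V, faces)
            assert err < 1e-9, (name, err)
            V = G.finish(V)
            faces, edges = G.hull_faces(V)
        st = G.solid_stats(V, require_regular=regular)
        exp = EXPECTED[name if family != 'Johnson' else jkey]
        assert (st['V'], st['E'], st['F']) == exp, (name, st, exp)
        cop = coplanarity_max(V, faces)
        assert cop < 1e-9, (name, cop)
        slug = name.replace(' ', '_')
        fn = f"{sid:03d}_{slug}.txt"
        with open(os.path.join(OUT, fn), 'w') as fh:
            fh.write(f"# {sid}|{name}|{family}\n")
            for p in V:
                fh.write("%.12g %.12g %.12g\n" % tuple(p))
        entries.append(dict(
            id=sid, name=name, family=family, file=fn,
            V=st['V'], E=st['E'], F=st['F'],
            face_hist={str(k): v for k, v in st['face_hist'].items()},
            degree_hist={str(k): v for k, v in st['degree_hist'].items()}))
        print(f"{sid:3d} {family:11s} {name:46s} V={st['V']:3d} E={st['E']:3d} F={st['F']:3d}")

    jkey = None
    for name, V in G.platonic().items():
        emit(name, 'Platonic', V)
    arch = archimedean()
    for name in ['truncated tetrahedron', 'cuboctahedron', 'truncated cube',
                 'truncated octahedron', 'rhombicuboctahedron',
                 'truncated cuboctahedron', 'snub cube', 'icosidodecahedron',
                 'truncated dodecahedron', 'truncated icosahedron',
                 'rhombicosidodecahedron', 'truncated icosidodecahedron',
                 'snub dodecahedron']:
        emit(name, 'Archimedean', arch[name])
    arch_fin = {k: G.finish(v) for k, v in arch.items()}
    # polish the two families' seeds before dualising so midspheres are exact
    for k in arch_fin:
        faces, _ = G.hull_faces(arch_fin[k])
        P, err = G.polish(arch_fin[k], faces)
        arch_fin[k] = G.finish(P)
    for cname, aname in CATALAN_OF:
        emit(cname, 'Catalan', G.dual_catalan(arch_fin[aname]), regular=False)
    sols = johnson_all()
    for k in range(1, 93):
        jkey = f'J{k}'
        emit(f'{JOHNSON_NAMES[jkey]} (J{k})', 'Johnson', sols[jkey])

    with open(os.path.join(OUT, 'manifest.json'), 'w') as fh:
        json.dump(entries, fh, separators=(',', ':'))
    print(f"\n{len(entries)} solids written to {OUT}")


if __name__ == '__main__':
    main()
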