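"""Search harness for the elementary Johnson solids.

Random starts of a symmetry template are pulled toward unit hull edges by
iterated freeze-and-refit; once the hull's face histogram matches the target,
the regular-face polisher takes over and the result is fully re-verified.
"""
import numpy as np
import geombuild as G
from scipy.optimize import least_squares


def search(build, sampler, target_hist, ntrials=400, rounds=12, seed=0,
           verbose=False):
    rng = np.random.default_rng(seed)
    for trial in range(ntrials):
        x = np.asarray(sampler(rng), float)
        try:
            for it in range(rounds):
                V = build(x)
                faces, edges = G.hull_faces(V, require_extreme=False)
                ii, jj = edges[:, 0], edges[:, 1]

                def resid(p):
                    P = build(p)
                    return np.linalg.norm(P[ii] - P[jj], axis=1) - 1.0

                sol = least_squares(resid, x, method='lm', xtol=1e-13, ftol=1e-13)
                stable = np.allclose(sol.x, x, atol=1e-12)
                x = sol.x
                V = build(x)
                faces2, _ = G.hull_faces(V, require_extreme=False)
                fh = {}
                for f in faces2:
                    fh[len(f)] = fh.get(len(f), 0) + 1
                if fh == target_hist:
                    P, err = G.polish(V, faces2)
                    if err < 1e-9:
                        st = G.solid_stats(G.finish(P))
                        if st['face_hist'] == target_hist:
                            return G.finish(P), st, trial
                if stable:
                    break
        except Exception:
            continue
    return None, None, None
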