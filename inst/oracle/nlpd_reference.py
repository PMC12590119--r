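"""Independent reference implementation of the normalized Laplacian
pyramid distance (NLPD), used as a cross-check oracle in the test suite.

Construction: Burt-Adelson Laplacian pyramid with a 5-tap binomial lowpass
([1,4,6,4,1]/16, separable, half-sample-symmetric 'reflect' boundary),
divisive normalization of each band-pass level by (c + local uniform mean
of |coefficients|), and the distance
    (1/N) * sum_k ||y_k - y~_k||_2 / Ns(k),
where the normalized lowpass residual enters as a final scale unless
disabled.

Usage:
    python nlpd_reference.py a.csv b.csv n_scales const pool_size [lowpass01]
prints the distance as a bare decimal on stdout.
"""
import sys

import numpy as np
from scipy.ndimage import correlate1d

K5 = np.array([1.0, 4.0, 6.0, 4.0, 1.0]) / 16.0


def blur(x, k):
    t = correlate1d(x, k, axis=0, mode="reflect")
    return correlate1d(t, k, axis=1, mode="reflect")


def upsample(dn, shape):
    # zero-stuff to the target shape; the margin reflects the coarse image
    # itself so constants are reproduced exactly at the border
    m = 2
    nr, nc = shape
    rows = np.arange(-m, nr + m)
    cols = np.arange(-m, nc + m)

    def ref(j, nd):
        j = np.where(j < 0, -j - 1, j)
        return np.where(j >= nd, 2 * nd - 1 - j, j)

    up = np.zeros((nr + 2 * m, nc + 2 * m))
    er = np.where(rows % 2 == 0)[0]
    ec = np.where(cols % 2 == 0)[0]
    rr = ref(rows[er] // 2, dn.shape[0])
    cc = ref(cols[ec] // 2, dn.shape[1])
    up[np.ix_(er, ec)] = dn[np.ix_(rr, cc)]
    out = blur(up, 2.0 * K5)
    return out[m:m + nr, m:m + nc]


def pyramid(x, n_scales):
    bands = []
    g = x
    for _ in range(n_scales):
        lo = blur(g, K5)
        dn = lo[::2, ::2]
        bands.append(g - upsample(dn, g.shape))
        g = dn
    return bands, g


def normalize(band, const, pool_size):
    pool = blur(np.abs(band), np.ones(pool_size) / pool_size)
    return band / (const + pool)


def nlpd(a, b, n_scales, const, pool_size, include_lowpass=True):
    ba, lpa = pyramid(a, n_scales)
    bb, lpb = pyramid(b, n_scales)
    if include_lowpass:
        ba.append(lpa)
        bb.append(lpb)
    ya = [normalize(band, const, pool_size) for band in ba]
    yb = [normalize(band, const, pool_size) for band in bb]
    total = 0.0
    for u, v in zip(ya, yb):
        total += np.linalg.norm((u - v).ravel()) / u.size
    return total / len(ya)


if __name__ == "__main__":
    a = np.loadtxt(sys.argv[1], delimiter=",")
    b = np.loadtxt(sys.argv[2], delimiter=",")
    n_scales = int(sys.argv[3])
    const = float(sys.argv[4])
    pool_size = int(sys.argv[5])
    include_lowpass = len(sys.argv) < 7 or sys.argv[6] != "0"
    print(repr(float(nlpd(a, b, n_scales, const, pool_size, include_lowpass))))
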