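"""Independent reference implementation of variational mode decomposition.

Transcribed directly from the published alternating-direction update
equations (full-spectrum formulation, mirror extension), kept deliberately
separate from the R implementation: this script exists only to produce
reference centre frequencies and mode powers for fixed fixtures, which are
frozen into the package's test suite as a cross-implementation oracle.

Run:  python vmd_reference.py
"""

import numpy as np


def vmd(f, alpha, tau, K, tol, max_iter, init_band_hz, fs):
    n = len(f)
    half = n // 2
    x = np.concatenate([f[:half][::-1], f, f[n - half:][::-1]])
    T = len(x)
    freqs = np.arange(T) / T - 0.5 - 1.0 / T

    f_hat = np.fft.fftshift(np.fft.fft(x))
    f_hat_plus = f_hat.copy()
    f_hat_plus[: T // 2] = 0

    omega = np.linspace(init_band_hz[0], init_band_hz[1], K) / fs
    u_hat = np.zeros((T, K), dtype=complex)
    lam = np.zeros(T, dtype=complex)

    for _ in range(max_iter):
        u_prev = u_hat.copy()
        for k in range(K):
            sum_uk = u_hat.sum(axis=1) - u_hat[:, k]
            u_hat[:, k] = (f_hat_plus - sum_uk - lam / 2) / (
                1 + alpha * (freqs - omega[k]) ** 2
            )
            pos = slice(T // 2, T)
            p = np.abs(u_hat[pos, k]) ** 2
            omega[k] = np.sum(freqs[pos] * p) / (np.sum(p) + np.finfo(float).eps)
        if tau > 0:
            lam = lam + tau * (u_hat.sum(axis=1) - f_hat_plus)
        num = np.sum(np.abs(u_hat - u_prev) ** 2, axis=0)
        den = np.sum(np.abs(u_prev) ** 2, axis=0) + np.finfo(float).eps
        if np.sum(num / den) < tol:
            break

    modes = np.zeros((n, K))
    for k in range(K):
        spec = u_hat[:, k].copy()
        full = np.zeros(T, dtype=complex)
        full[T // 2:] = spec[T // 2:]
        full[1: T // 2 + 1] = np.conj(spec[T // 2:][::-1])
        modes[:, k] = np.real(np.fft.ifft(np.fft.ifftshift(full)))[half: half + n]
    return modes, omega * fs


def clustered_report(modes, cf, tol=0.1):
    """Aggregate mode powers whose centre frequencies lie within tol Hz."""
    order = np.argsort(cf)
    cf_s = cf[order]
    pow_s = np.mean(modes[:, order] ** 2, axis=0)
    clusters = np.concatenate([[0], np.cumsum(np.diff(cf_s) > tol)])
    out = []
    for c in np.unique(clusters):
        m = clusters == c
        w = pow_s[m]
        if w.sum() == 0:
            continue
        # power of the aggregate = power of the summed time-domain modes
        agg = modes[:, order][:, m].sum(axis=1)
        out.append((np.sum(cf_s[m] * w) / w.sum(), np.mean(agg ** 2)))
    out.sort(key=lambda p: -p[1])
    return out


def lcg_uniform(seed, n):
    """Portable LCG (same arithmetic as the R test helper)."""
    state = seed
    out = np.empty(n)
    for i in range(n):
        state = (1103515245 * state + 12345) % 2147483648
        out[i] = state / 2147483648.0
    return out


def fixture(seed):
    fs = 20.0
    t = np.arange(int(60 * fs)) / fs
    u = lcg_uniform(seed, 3 + len(t))
    ph = 2 * np.pi * u[:3]
    noise = 0.05 * (u[3:] - 0.5)
    x = (
        np.sin(2 * np.pi * 1.1 * t + ph[0])
        + 0.7 * np.sin(2 * np.pi * 2.6 * t + ph[1])
        + 0.4 * np.sin(2 * np.pi * 4.3 * t + ph[2])
        + noise
    )
    return x, fs


if __name__ == "__main__":
    for seed in (101, 102, 103):
        x, fs = fixture(seed)
        modes, cf = vmd(x, alpha=2000, tau=0, K=10, tol=1e-7,
                        max_iter=500, init_band_hz=(0.8, 6.0), fs=fs)
        top = clustered_report(modes, cf)[:3]
        top.sort(key=lambda p: p[0])
        total = sum(p for _, p in top)
        print(f"seed {seed}:")
        for c, p in top:
            print(f"  cf={c:.4f} Hz  power_frac={p / total:.4f}")
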