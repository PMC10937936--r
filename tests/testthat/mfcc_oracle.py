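"""Independent MFCC reference implementation (numpy/scipy).

Reads a one-column CSV of samples, computes 13 MFCCs with the documented
settings (200-sample Hamming frames, hop 100, 512-point FFT, 26 HTK mel
filters 0..fs/2, log floor 1e-10, orthonormal DCT-II) and writes a CSV
with per-coefficient mean and standard deviation.

Usage: python mfcc_oracle.py <in_samples.csv> <fs> <out.csv>
"""
import sys

import numpy as np
from scipy.fft import dct

def mel(f):
    return 2595.0 * np.log10(1.0 + f / 700.0)

def imel(m):
    return 700.0 * (10.0 ** (m / 2595.0) - 1.0)

def main(path_in, fs, path_out):
    x = np.loadtxt(path_in)
    fs = float(fs)
    win, hop, nfft, n_mel, n_mfcc = 200, 100, 512, 26, 13
    w = np.hamming(win)
    starts = np.arange(0, len(x) - win + 1, hop)
    frames = np.stack([x[s:s + win] * w for s in starts], axis=1)
    spec = np.abs(np.fft.rfft(frames, n=nfft, axis=0)) ** 2

    edges = imel(np.linspace(mel(0.0), mel(fs / 2.0), n_mel + 2))
    freqs = np.arange(nfft // 2 + 1) * fs / nfft
    fb = np.zeros((n_mel, len(freqs)))
    for m in range(n_mel):
        lo, ce, hi = edges[m], edges[m + 1], edges[m + 2]
        up = (freqs - lo) / (ce - lo)
        dn = (hi - freqs) / (hi - ce)
        fb[m] = np.maximum(0.0, np.minimum(up, dn))

    loge = np.log(np.maximum(fb @ spec, 1e-10))
    cep = dct(loge, type=2, axis=0, norm="ortho")[:n_mfcc]
    out = np.column_stack([cep.mean(axis=1), cep.std(axis=1, ddof=1)])
    np.savetxt(path_out, out, delimiter=",", header="mean,sd", comments="")

if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], sys.argv[3])
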