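"""Independent reference run of the one-sample spatio-spectral cluster
permutation test (MNE), used only as a cross-check oracle by the test suite.

Usage: python mne_cluster.py <in.json> <out.json>

in.json: {"x": [[...]], "n_ch": int, "n_freq": int, "threshold": float}
         where x is flies x (n_ch*n_freq), frequency-fastest cell order.
out.json: {"labels": [...], "p": [...]} with labels a cell vector of cluster
          ids (0 = none) in the same cell order and p per cluster id.
"""
import json
import sys

import numpy as np
from mne.stats import combine_adjacency, permutation_cluster_1samp_test


def main(inp, outp):
    with open(inp) as fh:
        spec = json.load(fh)
    n_ch, n_freq = spec["n_ch"], spec["n_freq"]
    x = np.asarray(spec["x"], dtype=float).reshape(-1, n_ch, n_freq)
    adj = combine_adjacency(n_ch, n_freq)
    t_obs, clusters, pvals, h0 = permutation_cluster_1samp_test(
        x,
        threshold=spec["threshold"],
        tail=0,
        adjacency=adj,
        n_permutations=2 ** x.shape[0] + 1,  # request the exact test
        out_type="mask",
        rng=0,
        verbose="error",
    )
    labels = np.zeros(n_ch * n_freq, dtype=int)
    for k, mask in enumerate(clusters, start=1):
        labels[np.asarray(mask).reshape(-1)] = k
    json.dump(
        {"labels": labels.tolist(), "p": np.asarray(pvals).tolist(),
         "n_permutations": int(len(h0))},
        open(outp, "w"),
    )


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
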