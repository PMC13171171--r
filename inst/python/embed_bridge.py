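"""UMAP + t-SNE projection of a PCA matrix.

Usage: python embed_bridge.py <pca.csv> <out.csv> <seed> <n_neighbors>

Reads a headerless CSV of PC coordinates (cells x dims), writes a CSV with
columns umap1,umap2,tsne1,tsne2. Deterministic given the seed.
"""
import sys

import numpy as np


def main():
    pca_file, out_file, seed, n_neighbors = sys.argv[1:5]
    seed = int(seed)
    x = np.loadtxt(pca_file, delimiter=",", ndmin=2)
    n = x.shape[0]

    import umap
    um = umap.UMAP(n_components=2, n_neighbors=min(int(n_neighbors), n - 1),
                   random_state=seed, n_jobs=1).fit_transform(x)

    from sklearn.manifold import TSNE
    perplexity = max(2.0, min(30.0, (n - 1) / 3.0))
    ts = TSNE(n_components=2, perplexity=perplexity, random_state=seed,
              init="pca").fit_transform(x)

    out = np.column_stack([um, ts])
    np.savetxt(out_file, out, delimiter=",",
               header="umap1,umap2,tsne1,tsne2", comments="", fmt="%.10g")


if __name__ == "__main__":
    main()
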