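"""Shuttle between a plain-text exchange directory and an .h5ad file.

Usage:
    python h5ad_bridge.py to_h5ad   <exchange_dir> <out.h5ad>
    python h5ad_bridge.py from_h5ad <in.h5ad> <exchange_dir>

The exchange directory holds X.mtx (+ optional S/U/A.mtx layers),
barcodes.tsv, genes.tsv (id [tab symbol]), optional obs.tsv (tab-separated,
header row) and optional uns.json. Numeric obs columns are written back
with 17 significant digits so doubles round-trip exactly.
"""
import json
import os
import sys

import numpy as np
import pandas as pd
import scipy.io
import scipy.sparse as sp
import anndata


def _read_exchange(xdir):
    X = sp.csr_matrix(scipy.io.mmread(os.path.join(xdir, "X.mtx")))
    with open(os.path.join(xdir, "barcodes.tsv")) as fh:
        barcodes = [l.rstrip("\n") for l in fh]
    genes, symbols = [], []
    with open(os.path.join(xdir, "genes.tsv")) as fh:
        for l in fh:
            parts = l.rstrip("\n").split("\t")
            genes.append(parts[0])
            symbols.append(parts[1] if len(parts) > 1 else "")
    layers = {}
    for name in ("S", "U", "A"):
        p = os.path.join(xdir, name + ".mtx")
        if os.path.exists(p):
            layers[name] = sp.csr_matrix(scipy.io.mmread(p))
    obs = pd.DataFrame(index=pd.Index(barcodes, name="barcode"))
    obs_path = os.path.join(xdir, "obs.tsv")
    if os.path.exists(obs_path):
        tab = pd.read_csv(obs_path, sep="\t", float_precision="round_trip")
        tab.index = obs.index
        obs = tab
    var = pd.DataFrame(index=pd.Index(genes, name="gene_id"))
    if any(symbols):
        var["gene_symbol"] = symbols
    uns = {}
    uns_path = os.path.join(xdir, "uns.json")
    if os.path.exists(uns_path):
        with open(uns_path) as fh:
            uns = json.load(fh)
    return X, obs, var, layers, uns


def to_h5ad(xdir, out_path):
    X, obs, var, layers, uns = _read_exchange(xdir)
    ad = anndata.AnnData(X=X.astype(np.float64), obs=obs, var=var)
    for name, mat in layers.items():
        ad.layers[name] = mat.astype(np.float64)
    ad.uns.update(uns)
    ad.write_h5ad(out_path)


def _jsonable(x):
    if isinstance(x, dict):
        return {k: _jsonable(v) for k, v in x.items()}
    if isinstance(x, (list, tuple)):
        return [_jsonable(v) for v in x]
    if isinstance(x, np.ndarray):
        return [_jsonable(v) for v in x.tolist()]
    if isinstance(x, (np.integer,)):
        return int(x)
    if isinstance(x, (np.floating,)):
        v = float(x)
        return None if np.isnan(v) else v
    if isinstance(x, (np.bool_,)):
        return bool(x)
    if isinstance(x, float) and np.isnan(x):
        return None
    return x


def from_h5ad(in_path, xdir):
    ad = anndata.read_h5ad(in_path)
    os.makedirs(xdir, exist_ok=True)
    X = ad.X
    if X is None:
        total = None
        for name in ("S", "U", "A"):
            if name in ad.layers:
                m = sp.csr_matrix(ad.layers[name])
                total = m if total is None else total + m
        X = total
    scipy.io.mmwrite(os.path.join(xdir, "X.mtx"),
                     sp.coo_matrix(X).astype(np.int64))
    for name in ("S", "U", "A"):
        if name in ad.layers:
            scipy.io.mmwrite(os.path.join(xdir, name + ".mtx"),
                             sp.coo_matrix(ad.layers[name]).astype(np.int64))
    with open(os.path.join(xdir, "barcodes.tsv"), "w") as fh:
        fh.write("\n".join(map(str, ad.obs_names)) + "\n")
    with open(os.path.join(xdir, "genes.tsv"), "w") as fh:
        if "gene_symbol" in ad.var.columns:
            for g, s in zip(ad.var_names, ad.var["gene_symbol"]):
                fh.write(f"{g}\t{s}\n")
        else:
            fh.write("\n".join(map(str, ad.var_names)) + "\n")
    if ad.obs.shape[1] > 0:
        ad.obs.to_csv(os.path.join(xdir, "obs.tsv"), sep="\t", index=False,
                      float_format="%.17g", na_rep="NA")
    with open(os.path.join(xdir, "uns.json"), "w") as fh:
        json.dump(_jsonable(dict(ad.uns)), fh)


def main():
    if len(sys.argv) != 4 or sys.argv[1] not in ("to_h5ad", "from_h5ad"):
        sys.exit(__doc__)
    if sys.argv[1] == "to_h5ad":
        to_h5ad(sys.argv[2], sys.argv[3])
    else:
        from_h5ad(sys.argv[2], sys.argv[3])


if __name__ == "__main__":
    main()
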