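"""Convert an h5ad file to the CSV bundle layout the R loader reads.

Usage: python h5ad_to_csv.py <input.h5ad> <outdir> [label_column]
Writes expression.csv (spots x genes, first column barcode) and coords.csv
(barcode,x,y[,label]) using the spatial slot obsm["spatial"].
"""
import sys
import os

import numpy as np
import anndata as ad


def main():
    if len(sys.argv) < 3:
        sys.exit("usage: h5ad_to_csv.py <input.h5ad> <outdir> [label_column]")
    path, outdir = sys.argv[1], sys.argv[2]
    label_col = sys.argv[3] if len(sys.argv) > 3 else None
    adata = ad.read_h5ad(path)
    if "spatial" not in adata.obsm:
        sys.exit("no spatial information: obsm['spatial'] missing")
    X = adata.X
    if not isinstance(X, np.ndarray):
        X = X.toarray()
    os.makedirs(outdir, exist_ok=True)
    barcodes = adata.obs_names.astype(str)
    genes = adata.var_names.astype(str)
    with open(os.path.join(outdir, "expression.csv"), "w") as fh:
        fh.write("barcode," + ",".join(genes) + "\n")
        for bc, row in zip(barcodes, X):
            fh.write(bc + "," + ",".join(repr(float(v)) for v in row) + "\n")
    sp = np.asarray(adata.obsm["spatial"], dtype=float)
    labels = None
    if label_col is not None:
        if label_col not in adata.obs.columns:
            sys.exit(f"label column {label_col!r} not found in obs")
        labels = adata.obs[label_col].astype(str).values
    with open(os.path.join(outdir, "coords.csv"), "w") as fh:
        fh.write("barcode,x,y" + (",label" if labels is not None else "") + "\n")
        for i, bc in enumerate(barcodes):
            row = f"{bc},{float(sp[i, 0])!r},{float(sp[i, 1])!r}"
            if labels is not None:
                row += "," + labels[i]
            fh.write(row + "\n")


if __name__ == "__main__":
    main()
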