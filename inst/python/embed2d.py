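"""2D embedding backend: lle|tsne infile outfile seed n_neighbors."""
import sys

import numpy as np
from sklearn.manifold import TSNE, LocallyLinearEmbedding

method, infile, outfile, seed, n_neighbors = sys.argv[1:6]
seed, n_neighbors = int(seed), int(n_neighbors)
x = np.loadtxt(infile, delimiter=",", ndmin=2)

if method == "lle":
    est = LocallyLinearEmbedding(
        n_neighbors=min(n_neighbors, x.shape[0] - 1),
        n_components=2,
        random_state=seed,
    )
elif method == "tsne":
    est = TSNE(
        n_components=2,
        perplexity=min(n_neighbors, (x.shape[0] - 1) / 3),
        random_state=seed,
        init="pca",
    )
else:
    sys.exit(f"unknown method: {method}")

np.savetxt(outfile, est.fit_transform(x), delimiter=",")
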