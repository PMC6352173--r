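# fdpca

Feature extraction and classification for electronic-nose (gas-sensor array)
data, built around **fuzzy discriminant principal component analysis
(FDPCA)**.

## The problem

An electronic nose couples an array of cross-sensitive metal-oxide gas
sensors to a pattern classifier: the steady-state response levels of the
sensors jointly fingerprint a volatile-compound mixture (a liquor's
headspace, a food aroma, ...). The hard part is that several product classes
can have nearly coincident fingerprints, so their clusters overlap in
feature space. Variance-ranked PCA features ignore class structure entirely;
crisp discriminant features (Fisher-type scatter ratios) treat every sample
as fully owned by its labelled class, which misrepresents exactly the
samples sitting in the overlap. FDPCA addresses this by letting soft class
memberships weight the scatter matrices.

This package is for chemometricians and sensor-array practitioners who need
the complete chain: raw response curves → steady-state features →
normalization → PCA / DPCA / FDPCA feature extraction → KNN classification
with leave-one-out and repeated stratified k-fold cross-validation — plus a
synthetic benchmark generator, since real datasets of this kind are rarely
deposited.

## The method

With fuzzy memberships `u_ik` (degree of sample `k` in class `i`, columns
summing to 1) estimated by the fuzzy K-nearest-neighbour rule, weight
exponent `m_f > 1`, fuzzy centers `v_i = Σ_k u_ik^{m_f} x_k / Σ_k u_ik^{m_f}`
and global mean `x̄`, FDPCA forms the fuzzy between-class and total scatters

    S_fB = Σ_i Σ_k u_ik^{m_f} (v_i − x̄)(v_i − x̄)ᵀ
    S_fT = Σ_i Σ_k u_ik^{m_f} (x_k − x̄)(x_k − x̄)ᵀ

and extracts `p` *fuzzy optimal discriminant vectors*: the dominant
eigenvector of `S_fT⁻¹ S_fB`, then repeatedly the dominant eigenvector of
the deflated operator `P S_fT⁻¹ S_fB` with
`P = I − S_fT⁻¹ Ψ Q⁻¹ Ψᵀ`, `Q = Ψᵀ S_fT⁻¹ Ψ`, which forces each new vector
to be orthogonal to all previous ones while maximizing the fuzzy scatter
ratio on that complement. DPCA is the crisp special case (within-class
scatter in the denominator, hard labels); with 0/1 memberships the two
methods provably span the same subspace, which the test suite verifies.

## Worked example

```r
library(fdpca)

# synthetic 6-class e-nose experiment: 25 samples/class, 10 sensors,
# three far classes and three overlapped ones (the default geometry)
cfg <- synthetic_config(per_class = 25, seed = 11)
tab <- generate_features(cfg)
tab
#> feature_table: 150 samples x 10 features, 6 classes (class_1, class_2, ...)

# five fuzzy optimal discriminant vectors
basis <- fdpca_fit(tab, p = 5)
basis
#> discriminant_basis: FDPCA, 10 x 5
#> eigenvalues: 0.96078 0.95457 0.95271 0.55076 0.51542

# paired comparison of the three extractors under the validation protocol
cmp <- compare_extractors(tab, pipeline_config(seed = 11),
                          folds = c(5, 10), repeats = 5)
cmp
#> method         LOO    5-fold   10-fold   average
#> PCA         66.00%    68.00%    69.47%    67.82%
#> DPCA        76.00%    84.53%    82.67%    81.07%
#> FDPCA       76.00%    80.80%    79.73%    78.84%
```

Reading the output: the FDPCA eigenvalues are fuzzy scatter ratios
`ψᵀS_fBψ / ψᵀS_fTψ ∈ [0, 1]` — three directions near 0.95 separate the three
far classes cleanly, the remaining two (~0.5) carry the harder overlapped
structure. In the comparison table each row is one extractor evaluated with
identical fold assignments; the discriminant methods recover roughly 11–13
accuracy points over PCA on this overlapped geometry, and every number is
reproducible from the seeds shown.

`project()` maps a table onto a basis for plotting (`plot_projected()`), and
`write_basis()` / `write_feature_table()` give exact-round-trip CSV
artifacts. A thin command-line front end with `simulate`, `preprocess`,
`extract`, `classify`, `crossval` and `plot3d` subcommands is installed at
`inst/cli/fdpca`.

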