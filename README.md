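# srsc — spatially regularized spectral clustering for multiparametric MRI

`srsc` is an R package for unsupervised segmentation of tumor tissue
populations — necrotic, peri-necrotic, and viable — from co-registered
multiparametric MRI volumes (ADC in 1e-6 mm²/s; quantitative T2 and T2*
maps in ms, before and after an iron-oxide contrast agent). It is aimed at
preclinical and translational imaging groups who need voxel-wise tissue
maps and per-tissue volume fractions from standard clinical-protocol
parameter maps, without training labels.

## The method

Each masked voxel carries the feature vector
x_i = (ADC, T2_pre, T2_post, T2*_pre, T2*_post). The SRSC pipeline:

1. z-score each parameter over the mask;
2. build the RBF affinity
   W_ij = exp(−‖x_i − x_j‖² / 2σ²) (i ≠ j), W_ii = 0,
   with σ from the median pairwise-distance heuristic;
3. embed the voxels with the eigenvectors of the k smallest eigenvalues of
   the symmetric normalized Laplacian L = I − D^{−1/2} W D^{−1/2}
   (default k = K + 1);
4. fit a Gaussian mixture by EM in which the E-step responsibility is
   r_ik ∝ π_k N(y_i | μ_k, Σ_k) · s_ik, where s_ik is the mean
   responsibility of voxel i's 26-connected neighbors in image space —
   a voxel is more likely to take a class its spatial neighbors carry;
5. name the classes by mean raw ADC: highest → necrotic, middle →
   peri-necrotic, lowest → viable.

The package also ships the three baselines the method is compared against
(K-means, fuzzy C-means, standard GMM), tissue-fraction computation with
Pearson-correlation validation against reference fractions, class-wise
nonparametric statistics (Kolmogorov–Smirnov normality, Kruskal–Wallis,
Bonferroni-corrected rank-sum at α = 0.0167), a seeded synthetic phantom
generator with ground truth, minimal NIfTI-1 I/O, and a CLI.

## Worked example

```r
library(srsc)

# a 24x24x12 synthetic tumor: necrotic core, peri-necrotic rim, viable
# shell; ADC class distributions at their reported values
ph  <- generate_phantom(phantom_spec(seed = 1))
seg <- run_segmentation(run_config(method = "srsc", seed = 1),
                        stack = ph$stack)
print(seg$fractions$fractions)
print(ph$fractions$fractions)
mm <- match_labels(seg$labels, ph$truth)
cat("accuracy", round(mm$accuracy, 3), "ARI", round(mm$ari, 3), "\n")
```

prints

```
       viable      necrotic peri-necrotic
    0.5993421     0.1529605     0.2476974
     necrotic peri-necrotic        viable
         0.15          0.25          0.60
accuracy 0.981 ARI 0.948
```

i.e. the recovered tissue fractions are within 0.3 percentage points of
the ground truth and 98.1% of voxels carry the correct label. The
segmentation object holds per-class probability volumes, per-class
parameter means/SDs, the RBF σ used, and the EM objective trace;
`write_segmentation()` writes the label volume, one probability volume per
class, and a JSON manifest, all NIfTI with the input affine.

Command line (installed under `inst/scripts/`):

```sh
srsc phantom --out /tmp/ph --seed 1
srsc run --map ADC=/tmp/ph/ADC.nii.gz,T2_pre=... --mask /tmp/ph/mask.nii.gz --out /tmp/seg
srsc eval --pred /tmp/seg/labels.nii.gz --truth /tmp/ph/truth.nii.gz
srsc compare --subjects 5 --seed 1 --out /tmp/cmp
```

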