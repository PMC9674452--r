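#!/usr/bin/env Rscript
# Stage 3: common-garden quantitative genetics.  Nested variance components
# (REML), heritability, evolvability, additive genetic SD and Q_ST with
# jackknife CIs under the mixed-mating kinship weight; per-population fits;
# one-sample t-tests of evolvability.

suppressPackageStartupMessages(library(fragpop))

dat <- "results/data"
out <- "results/quantgen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

traits <- read.csv(file.path(dat, "traits.csv"))
transforms <- c(diameter = "none", leaf_width = "none", flowers = "sqrt")

qs <- quantgen_summary(traits, transforms, selfing_fraction = 0.55)
cat(sprintf("Kinship weight theta = %.4f (55%% selfing)\n", qs$theta))
print(qs$global[, c("trait", "v_pop", "v_fam", "v_error", "h2",
                    "cv_genetic", "qst", "qst_lo", "qst_hi")],
      row.names = FALSE, digits = 3)
write.csv(qs$global, file.path(out, "global.csv"), row.names = FALSE)

for (trait in names(qs$per_population)) {
  pp <- qs$per_population[[trait]]
  write.csv(pp, file.path(out, sprintf("per_population_%s.csv", trait)),
            row.names = FALSE)
  tt <- one_sample_t(pp$cv_genetic)
  cat(sprintf("Evolvability of %s: mean %.1f%%, t(%d) = %.1f, p = %.2g\n",
              trait, 100 * tt$mean, tt$df, tt$t, tt$p))
}

# evolvability vs heritability across populations, per trait and averaged
cv_mat <- sapply(qs$per_population, function(df) df$cv_genetic)
h2_mat <- sapply(qs$per_population, function(df) df$h2)
for (trait in colnames(cv_mat)) {
  r <- correlate(cv_mat[, trait], h2_mat[, trait])
  cat(sprintf("CV_genetic vs h2 for %s: r = %.2f (p = %.2g)\n",
              trait, r$r, r$p))
}
r_mean <- correlate(rowMeans(cv_mat), rowMeans(h2_mat))
cat(sprintf("Mean CV_genetic vs mean h2: r = %.2f (p = %.2g)\n",
            r_mean$r, r_mean$p))
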