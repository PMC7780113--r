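#!/usr/bin/env Rscript
# Calibrates the bond-type resonance factors k_beta against a target
# S0->S1 wavelength for a reference fragment: a single global scale s is
# fitted so that lambda1(s * k_beta) matches the target, and the scaled
# table is written as a YAML parameter file usable via indo_params(file).
#
# Usage: Rscript scripts/calibrate_kbeta.R --target-nm <lambda> \
#          [--fragment <xyz file>] [--out <yaml>] [--n-singles <N>]

suppressMessages(library(phycospec))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(target = NULL, fragment = NULL,
            out = "calibrated_params.yaml", n_singles = 60)
i <- 1
while (i <= length(args)) {
  key <- args[i]
  if (key == "--target-nm") opt$target <- as.numeric(args[i + 1])
  else if (key == "--fragment") opt$fragment <- args[i + 1]
  else if (key == "--out") opt$out <- args[i + 1]
  else if (key == "--n-singles") opt$n_singles <- as.integer(args[i + 1])
  else stop("unknown argument: ", key)
  i <- i + 2
}
if (is.null(opt$target)) stop("--target-nm is required")

frag <- if (is.null(opt$fragment)) {
  make_pcb_surrogate(protonated = TRUE)$fragment
} else {
  read_xyz(opt$fragment)
}

base <- indo_params()
lambda_at <- function(s) {
  kb <- lapply(base$k_beta, function(v) v * s)
  p <- indo_params(k_beta = kb)
  compute_spectrum(frag, p, n_singles = opt$n_singles,
                   n_states = 1)$states$wavelength_nm[1]
}

obj <- function(s) (lambda_at(s) - opt$target)^2
fit <- stats::optimize(obj, interval = c(0.5, 1.6))
s_best <- fit$minimum
lam_best <- lambda_at(s_best)
cat(sprintf("scale = %.4f  lambda1 = %.1f nm (target %.1f nm)\n",
            s_best, lam_best, opt$target))

out <- base
out$k_beta <- lapply(base$k_beta, function(v) v * s_best)
write_params_yaml(out, opt$out)
cat("wrote", opt$out, "\n")
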