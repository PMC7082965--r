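# Synthetic data generators: planted co-expression modules (latent-factor
# construction) and negative-binomial counts with condition x timepoint
# differential-expression effects. These give the pipeline inputs with the
# statistical structure it assumes, at desk scale.

#' Simulate an expression matrix with planted co-expression modules
#'
#' Each module is built from one latent factor (its eigengene): a standard
#' normal profile \\eqn{f} across samples shared by the module, with member
#' genes \\eqn{x_{ij} = \\sqrt{\\rho} f_j + \\sqrt{1-\\rho}\\,\\epsilon_{ij}}
#' so that the expected within-module correlation is \\eqn{\\rho}. Noise
#' genes are independent standard normals and belong to no module.
#'
#' @param sizes Integer vector of module sizes (each >= 2).
#' @param within_correlation Target within-module correlation \\eqn{\\rho}
#'   in (0, 1\\]. Default 0.95.
#' @param n_noise_genes Number of unstructured noise genes (default 0).
#' @param n_samples Number of samples (default 30).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return List with `expr` (matrix, genes x samples) and `truth`
#'   (a [module_partition()]; noise genes are unassigned).
#' @export
simulate_modular_expression <- function(sizes, within_correlation = 0.95,
                                        n_noise_genes = 0L, n_samples = 30L,
                                        seed = NULL) {
  .check(length(sizes) >= 1L && all(sizes >= 2L), "module sizes must all be >= 2")
  .check(within_correlation > 0 && within_correlation <= 1,
         "`within_correlation` must be in (0, 1]")
  .check(n_noise_genes >= 0L, "`n_noise_genes` must be >= 0")
  .check(n_samples >= 3L, "need at least 3 samples")
  with_seed(seed, {
    n_mod_genes <- sum(sizes)
    n <- n_mod_genes + n_noise_genes
    rho <- within_correlation
    expr <- matrix(NA_real_, n, n_samples)
    labels <- integer(n)
    row <- 1L
    for (m in seq_along(sizes)) {
      f <- rnorm(n_samples)
      for (g in seq_len(sizes[m])) {
        expr[row, ] <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_samples)
        labels[row] <- m
        row <- row + 1L
      }
    }
    if (n_noise_genes > 0L) {
      expr[row:n, ] <- matrix(rnorm(n_noise_genes * n_samples),
                              n_noise_genes, n_samples)
    }
    rownames(expr) <- sprintf("gene%04d", seq_len(n))
    colnames(expr) <- sprintf("sample%02d", seq_len(n_samples))
    names(labels) <- rownames(expr)
    list(expr = expr, truth = module_partition(labels))
  })
}

#' Simulate negative-binomial RNA-seq counts with DE effects
#'
#' Generates counts for two groups (control and treated) at several
#' timepoints, `n_per_group` replicates per group and timepoint. Gene
#' baseline means are drawn log-normal; a fixed fraction of genes is
#' differentially expressed, shifted in the treated group by
#' `log2_fc_effect` (sign drawn per gene) at every timepoint; library-size
#' factors are log-normal; counts are negative binomial with constant
#' dispersion.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Replicates per group per timepoint (default 3, the
#'   usual serial-sacrifice design).
#' @param timepoints Character vector of timepoint labels (default five
#'   monthly labels).
#' @param de_fraction Fraction of genes differentially expressed, in
#'   \\[0, 1\\] (default 0.1).
#' @param log2_fc_effect Absolute log2 fold change of DE genes (default 2).
#' @param nb_dispersion Negative-binomial dispersion (1/size, default 0.1).
#' @param seed Integer seed, or `NULL`.
#' @return List with `counts` (genes x samples), `samples` (data.frame of
#'   sample metadata: `sample`, `group`, `timepoint`), and `truth`
#'   (data.frame `gene_id`, `is_de`, `log2_fc`).
#' @export
simulate_counts <- function(n_genes = 500L, n_per_group = 3L,
                            timepoints = c("1m", "2m", "4m", "9m", "12m"),
                            de_fraction = 0.1, log2_fc_effect = 2,
                            nb_dispersion = 0.1, seed = NULL) {
  .check(de_fraction >= 0 && de_fraction <= 1, "`de_fraction` must be in [0, 1]")
  .check(nb_dispersion > 0, "`nb_dispersion` must be > 0")
  .check(n_per_group >= 2L, "need at least 2 replicates per group")
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    base_mu <- exp(rnorm(n_genes, mean = log(100), sd = 1.2))
    n_de <- round(de_fraction * n_genes)
    is_de <- c(rep(TRUE, n_de), rep(FALSE, n_genes - n_de))
    sign_de <- ifelse(runif(n_genes) < 0.5, 1, -1)
    lfc <- ifelse(is_de, sign_de * log2_fc_effect, 0)
    samples <- expand.grid(replicate = seq_len(n_per_group),
                           group = c("control", "treated"),
                           timepoint = timepoints,
                           stringsAsFactors = FALSE)
    samples$sample <- sprintf("%s_%s_r%d", samples$group, samples$timepoint,
                              samples$replicate)
    sf <- exp(rnorm(nrow(samples), 0, 0.15))
    counts <- matrix(0L, n_genes, nrow(samples),
                     dimnames = list(genes, samples$sample))
    size <- 1 / nb_dispersion
    for (s in seq_len(nrow(samples))) {
      mu <- base_mu * sf[s]
      if (samples$group[s] == "treated") mu <- mu * 2^lfc
      counts[, s] <- rnbinom(n_genes, size = size, mu = mu)
    }
    list(counts = counts,
         samples = samples[, c("sample", "group", "timepoint")],
         truth = data.frame(gene_id = genes, is_de = is_de, log2_fc = lfc,
                            stringsAsFactors = FALSE))
  })
}

#' Simple per-timepoint DE test on simulated counts
#'
#' A deliberately plain two-sample test used to turn simulated counts into
#' DE tables for end-to-end runs: log2-transformed library-size-normalized
#' counts (`log2(count/libsize-factor + 0.5)`), a Wald statistic on the
#' difference of group means with a pooled variance and a normal reference
#' distribution, and Benjamini-Hochberg adjustment within each timepoint.
#' This is not equivalent to a negative-binomial GLM analysis (no dispersion
#' shrinkage, no exact or quasi-likelihood test) and is intended only for
#' synthetic data.
#'
#' @param counts Count matrix, genes x samples.
#' @param samples Sample metadata as returned by [simulate_counts()].
#' @return Named list of [de_table()] objects, one per timepoint.
#' @export
de_test_lognormal <- function(counts, samples) {
  .check(ncol(counts) == nrow(samples), "counts/sample metadata mismatch")
  sf <- colSums(counts)
  sf <- sf / mean(sf)
  logx <- log2(sweep(counts, 2L, sf, "/") + 0.5)
  out <- lapply(unique(samples$timepoint), function(tp) {
    idx_t <- which(samples$timepoint == tp & samples$group == "treated")
    idx_c <- which(samples$timepoint == tp & samples$group == "control")
    .check(length(idx_t) >= 2L && length(idx_c) >= 2L,
           "need >= 2 replicates per group at each timepoint")
    xt <- logx[, idx_t, drop = FALSE]
    xc <- logx[, idx_c, drop = FALSE]
    diff <- rowMeans(xt) - rowMeans(xc)
    v <- (apply(xt, 1L, var) + apply(xc, 1L, var)) / 2
    se <- sqrt(v * (1 / length(idx_t) + 1 / length(idx_c)))
    se[se == 0] <- min(se[se > 0], 1e-8)
    z <- diff / se
    p <- 2 * pnorm(-abs(z))
    de_table(rownames(counts), diff, p, p.adjust(p, method = "BH"),
             comparison = tp)
  })
  names(out) <- unique(samples$timepoint)
  out
}
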