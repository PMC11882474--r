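#' Configuration for the synthetic snRNA-seq generator
#'
#' Builds and validates the parameter set for [generate_dataset()]. Defaults
#' emulate the study design the pipeline is aimed at: a 2 x 2 stress-by-wheel
#' layout with 6 individuals per group, negative-binomial counts with
#' per-gene dispersion, lognormal library sizes with a median around 2000
#' UMIs per nucleus, a small mitochondrial count share, planted marker-gene
#' clusters, a transcriptional-breadth (maturity) gradient, and a running
#' model in which acute stress suppresses 6-week wheel-running distance to
#' 14.9% of the unstressed level.
#'
#' @param n_genes number of genes.
#' @param n_nuclei number of nuclei (barcodes) before QC.
#' @param n_individuals_per_group individuals per treatment group.
#' @param groups data.frame with columns `stress` and `wheel` (0/1), one row
#'   per treatment group.
#' @param n_clusters number of planted cell clusters.
#' @param cluster_proportions simplex weights over clusters (default equal).
#' @param marker_genes_per_cluster disjoint marker genes per cluster.
#' @param marker_log2fc log2 fold elevation of a cluster's markers.
#' @param treatment_effect_genes named list; elements `stress`, `wheel`,
#'   `interaction` and/or `distance`, each a data.frame with columns `gene`
#'   (index or name) and `log2fc`. `distance` effects scale with the
#'   standardised 6-week running distance of the nucleus's individual.
#' @param individual_sd SD of the per-individual random intercept on the log
#'   mean (applied multiplicatively to every gene of the nucleus).
#' @param dispersion_range range (lo, hi) of per-gene NB size parameter theta.
#' @param library_logmean,library_logsd lognormal library-size parameters.
#' @param mito_gene_fraction fraction of genes given the mitochondrial prefix.
#' @param mito_count_share expected share of counts on mitochondrial genes.
#' @param mito_prefix gene-name prefix marking mitochondrial genes.
#' @param maturity_gradient logical; plant a per-nucleus expression-breadth
#'   gradient (broader = less differentiated).
#' @param breadth_range fraction of the gene universe expressed by the
#'   narrowest and broadest nuclei when the gradient is on.
#' @param qc_violators named integer vector with entries `low_umi`,
#'   `low_gene`, `high_umi`, `high_gene`, `high_mito`: numbers of barcodes
#'   planted to violate exactly one QC rule each.
#' @param qc_reference [qc_thresholds()] object the violators are planted
#'   against.
#' @param running_baseline_mean,running_baseline_sd per-individual 6-week
#'   distance baseline (km) for wheel-access animals.
#' @param suppression_factor multiplier on running distance under stress
#'   (in (0, 1]; default 0.149).
#' @param running_noise_sd additive noise SD (km) on the 6-week distance.
#' @param seed integer root seed; all randomness flows from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000,
                         n_nuclei = 4000,
                         n_individuals_per_group = 6,
                         groups = data.frame(stress = c(0, 0, 1, 1),
                                             wheel  = c(0, 1, 0, 1)),
                         n_clusters = 3,
                         cluster_proportions = NULL,
                         marker_genes_per_cluster = 25,
                         marker_log2fc = 2,
                         treatment_effect_genes = list(),
                         individual_sd = 0.3,
                         dispersion_range = c(0.5, 10),
                         library_logmean = log(2000),
                         library_logsd = 0.45,
                         mito_gene_fraction = 0.01,
                         mito_count_share = 0.015,
                         mito_prefix = "Mt-",
                         maturity_gradient = TRUE,
                         breadth_range = c(0.4, 0.95),
                         qc_violators = c(low_umi = 0, low_gene = 0,
                                          high_umi = 0, high_gene = 0,
                                          high_mito = 0),
                         qc_reference = qc_thresholds(),
                         running_baseline_mean = 180,
                         running_baseline_sd = 35,
                         suppression_factor = 0.149,
                         running_noise_sd = 8,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_nuclei = as.integer(n_nuclei),
              n_individuals_per_group = as.integer(n_individuals_per_group),
              groups = groups,
              n_clusters = as.integer(n_clusters),
              cluster_proportions = cluster_proportions %||%
                rep(1 / n_clusters, n_clusters),
              marker_genes_per_cluster = as.integer(marker_genes_per_cluster),
              marker_log2fc = marker_log2fc,
              treatment_effect_genes = treatment_effect_genes,
              individual_sd = individual_sd,
              dispersion_range = dispersion_range,
              library_logmean = library_logmean,
              library_logsd = library_logsd,
              mito_gene_fraction = mito_gene_fraction,
              mito_count_share = mito_count_share,
              mito_prefix = mito_prefix,
              maturity_gradient = isTRUE(maturity_gradient),
              breadth_range = breadth_range,
              qc_violators = qc_violators,
              qc_reference = qc_reference,
              running_baseline_mean = running_baseline_mean,
              running_baseline_sd = running_baseline_sd,
              suppression_factor = suppression_factor,
              running_noise_sd = running_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (cfg$n_genes < 1 || cfg$n_nuclei < 1)
    stopf("config error: n_genes and n_nuclei must be positive")
  if (abs(sum(cfg$cluster_proportions) - 1) > 1e-9)
    stopf("config error: cluster_proportions must sum to 1")
  if (any(cfg$cluster_proportions < 0))
    stopf("config error: cluster_proportions must be nonnegative")
  if (!all(c("stress", "wheel") %in% names(cfg$groups)))
    stopf("config error: groups needs stress and wheel columns")
  if (cfg$suppression_factor <= 0 || cfg$suppression_factor > 1)
    stopf("config error: suppression_factor must lie in (0, 1]")
  if (cfg$n_clusters * cfg$marker_genes_per_cluster >
        cfg$n_genes * (1 - cfg$mito_gene_fraction))
    stopf("config error: marker genes exceed the non-mitochondrial gene count")
  if (cfg$individual_sd < 0) stopf("config error: individual_sd must be >= 0")
  if (length(cfg$dispersion_range) != 2 || any(cfg$dispersion_range <= 0))
    stopf("config error: dispersion_range must be two positive numbers")
  need <- c("low_umi", "low_gene", "high_umi", "high_gene", "high_mito")
  if (!all(need %in% names(cfg$qc_violators)))
    stopf("config error: qc_violators needs entries %s",
          paste(need, collapse = ", "))
  cfg$qc_violators <- cfg$qc_violators[need]
  if (any(cfg$qc_violators < 0)) stopf("config error: negative violator count")
  if (cfg$qc_violators[["high_gene"]] > 0 &&
        cfg$n_genes <= cfg$qc_reference$max_genes)
    stopf("config error: cannot plant high-gene violators with n_genes <= %d",
          cfg$qc_reference$max_genes)
  if (sum(cfg$qc_violators) >= cfg$n_nuclei)
    stopf("config error: more QC violators than nuclei")
  if (length(cfg$breadth_range) != 2 || cfg$breadth_range[1] <= 0 ||
        cfg$breadth_range[2] > 1 || diff(cfg$breadth_range) < 0)
    stopf("config error: breadth_range must be increasing within (0, 1]")
  cfg
}

## resolve gene indices/names in a treatment-effect table
resolve_genes <- function(gene, gene_ids) {
  if (is.numeric(gene)) {
    idx <- as.integer(gene)
    if (any(idx < 1 | idx > length(gene_ids)))
      stopf("config error: treatment effect gene index out of range")
    idx
  } else {
    idx <- match(gene, gene_ids)
    if (anyNA(idx)) stopf("config error: unknown treatment effect gene")
    idx
  }
}

#' Generate a synthetic snRNA-seq dataset with known truth
#'
#' Draws a sparse gene x nucleus count matrix from the generative model the
#' downstream pipeline assumes: per-nucleus means are `library_size *
#' exp(u_individual) * p_g`, where `p_g` is a softmax over genes of a base
#' profile plus cluster-marker boosts and treatment log-fold effects, and
#' counts are negative binomial with gene-specific dispersion. A maturity
#' gradient is realised by varying the number of expressed genes per nucleus
#' (a nested breadth order), and QC violators are planted with exactly one
#' violation type each so survivor arithmetic is exact.
#'
#' @param config a [synth_config()].
#' @return list with components
#'   \describe{
#'     \item{counts}{`dgCMatrix`, genes x barcodes.}
#'     \item{meta}{data.frame keyed by barcode: pool, individual, stress,
#'       wheel and running-distance columns broadcast from the individual.}
#'     \item{truth}{list of data.frames `nuclei`, `genes`, `individuals`
#'       holding the planted ground truth.}
#'     \item{config}{the config, with the seed recorded.}
#'   }
#' @export
generate_dataset <- function(config) {
  cfg <- validate_synth_config(config)
  set.seed(cfg$seed)
  G <- cfg$n_genes; N <- cfg$n_nuclei

  ## --- genes -------------------------------------------------------------
  n_mito <- round(cfg$mito_gene_fraction * G)
  gene_ids <- sprintf("gene%05d", seq_len(G))
  mito_idx <- integer(0)
  if (n_mito > 0) {
    mito_idx <- seq_len(n_mito)
    gene_ids[mito_idx] <- sprintf("%sgene%05d", cfg$mito_prefix, mito_idx)
  }
  base <- rnorm(G, mean = 0, sd = 1.2)
  theta <- runif(G, cfg$dispersion_range[1], cfg$dispersion_range[2])

  non_mito <- setdiff(seq_len(G), mito_idx)
  K <- cfg$n_clusters
  marker_of <- integer(G)              # 0 = not a marker
  mk <- cfg$marker_genes_per_cluster
  if (mk > 0 && K > 0) {
    pool <- non_mito[seq_len(K * mk)]
    marker_of[pool] <- rep(seq_len(K), each = mk)
  }

  ## --- individuals -------------------------------------------------------
  grp <- cfg$groups
  n_grp <- nrow(grp)
  nipg <- cfg$n_individuals_per_group
  n_ind <- n_grp * nipg
  ind <- data.frame(
    individual = sprintf("ind%02d", seq_len(n_ind)),
    group = rep(seq_len(n_grp), each = nipg),
    stress = rep(grp$stress, each = nipg),
    wheel = rep(grp$wheel, each = nipg),
    intercept = rnorm(n_ind, 0, cfg$individual_sd),
    stringsAsFactors = FALSE)
  base_run <- pmax(rnorm(n_ind, cfg$running_baseline_mean,
                         cfg$running_baseline_sd), 5)
  supp <- ifelse(ind$stress == 1, cfg$suppression_factor, 1)
  d40 <- pmax(base_run * supp + rnorm(n_ind, 0, cfg$running_noise_sd), 0)
  d40[ind$wheel == 0] <- 0
  ## shorter windows: noisy shares of the 6-week total (positively correlated)
  frac <- function(f, sdlog = 0.4) d40 * f * exp(rnorm(n_ind, 0, sdlog))
  ind$dist_40d <- d40
  ind$dist_24h <- frac(1 / 42)
  ind$dist_3h <- frac(1 / 42 / 8, 0.6)
  ind$dist_30_90m <- frac(1 / 42 / 24, 0.8)
  ind$dist_30m <- frac(1 / 42 / 48, 1.0)

  ## --- nuclei ------------------------------------------------------------
  barcode <- sprintf("bc%06d", seq_len(N))
  nuc_ind <- sample(rep_len(seq_len(n_ind), N))
  cluster <- sample(seq_len(K), N, replace = TRUE,
                    prob = cfg$cluster_proportions)
  maturity_rank <- runif(N)
  lib <- rlnorm(N, cfg$library_logmean, cfg$library_logsd)

  ## --- per-nucleus gene weights ------------------------------------------
  ## log-weight = base + marker boost (cluster) + treatment effects
  lw <- matrix(base, nrow = G, ncol = N)
  if (mk > 0)
    for (k in seq_len(K)) {
      sel <- cluster == k
      if (any(sel))
        lw[marker_of == k, sel] <- lw[marker_of == k, sel] +
          cfg$marker_log2fc * log(2)
    }
  te <- cfg$treatment_effect_genes
  stress_n <- ind$stress[nuc_ind]
  wheel_n <- ind$wheel[nuc_ind]
  dist_scaled <- as.numeric(scale(ind$dist_40d))[nuc_ind]
  add_effect <- function(lw, tab, weight_n) {
    gi <- resolve_genes(tab$gene, gene_ids)
    on <- which(weight_n != 0)
    if (length(on))
      lw[gi, on] <- lw[gi, on] + outer(tab$log2fc * log(2), weight_n[on])
    lw
  }
  if (!is.null(te$stress)) lw <- add_effect(lw, te$stress, stress_n)
  if (!is.null(te$wheel)) lw <- add_effect(lw, te$wheel, wheel_n)
  if (!is.null(te$interaction))
    lw <- add_effect(lw, te$interaction, stress_n * wheel_n)
  if (!is.null(te$distance)) lw <- add_effect(lw, te$distance, dist_scaled)

  W <- exp(lw)

  ## breadth gradient: nested expressed-gene sets ordered by base abundance;
  ## markers of the nucleus's own cluster and mito genes always expressed
  if (cfg$maturity_gradient) {
    breadth <- cfg$breadth_range[1] +
      maturity_rank * diff(cfg$breadth_range)
    ord <- order(base, decreasing = TRUE)         # fixed ubiquity order
    rank_in_ord <- integer(G); rank_in_ord[ord] <- seq_len(G)
    n_expr <- pmax(ceiling(breadth * G), 1L)
    keep_rank <- matrix(rank_in_ord, nrow = G, ncol = N) <=
      matrix(n_expr, nrow = G, ncol = N, byrow = TRUE)
    always <- mito_idx
    keep_rank[always, ] <- TRUE
    if (mk > 0)
      for (k in seq_len(K)) {
        sel <- cluster == k
        if (any(sel)) keep_rank[marker_of == k, sel] <- TRUE
      }
    W <- W * keep_rank
  }

  ## mitochondrial share fixed at mito_count_share
  if (length(mito_idx)) {
    s <- cfg$mito_count_share
    msum <- colSums(W[mito_idx, , drop = FALSE])
    osum <- colSums(W[non_mito, , drop = FALSE])
    W[mito_idx, ] <- sweep(W[mito_idx, , drop = FALSE], 2, s / msum, `*`)
    W[non_mito, ] <- sweep(W[non_mito, , drop = FALSE], 2,
                           (1 - s) / osum, `*`)
  } else {
    W <- sweep(W, 2, colSums(W), `/`)
  }

  planted_lib <- lib * exp(ind$intercept[nuc_ind])
  mu <- sweep(W, 2, planted_lib, `*`)
  counts <- matrix(rnbinom(G * N, mu = as.vector(mu),
                           size = rep(theta, N)), nrow = G)

  ## --- planted QC violators ---------------------------------------------
  nv <- cfg$qc_violators
  total_v <- sum(nv)
  violation <- rep("none", N)
  if (total_v > 0) {
    vi <- (N - total_v + 1):N
    types <- rep(names(nv), times = nv)
    violation[vi] <- types
    thr <- cfg$qc_reference
    for (j in seq_along(vi)) {
      cidx <- vi[j]
      p <- W[, cidx]
      tot <- switch(types[j],
        low_umi = sample(200:(thr$min_umi - 200), 1),
        low_gene = round(runif(1, thr$min_umi * 1.3, thr$min_umi * 2.5)),
        high_umi = round(runif(1, thr$max_umi * 1.5, thr$max_umi * 2.5)),
        high_gene = round(runif(1, thr$max_genes * 1.6, thr$max_umi * 0.9)),
        high_mito = round(exp(cfg$library_logmean) * 1.2))
      if (types[j] == "low_gene") {
        ## confine counts to few genes, keep totals legal
        top <- order(p, decreasing = TRUE)[seq_len(min(200, G))]
        p2 <- numeric(G); p2[top] <- p[top]
        p <- p2 / sum(p2)
      }
      if (types[j] == "high_gene") {
        p <- rep(1 / G, G)            # spread thin to detect many genes
      }
      if (types[j] == "high_mito") {
        p[mito_idx] <- p[mito_idx] / sum(p[mito_idx]) * 0.25
        p[non_mito] <- p[non_mito] / sum(p[non_mito]) * 0.75
      }
      counts[, cidx] <- as.vector(rmultinom(1, tot, p))
      planted_lib[cidx] <- tot
    }
  }

  dimnames(counts) <- list(gene_ids, barcode)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")

  pool <- sprintf("pool%d", ((nuc_ind - 1) %% 4) + 1)
  meta <- data.frame(
    barcode = barcode, pool = pool,
    individual = ind$individual[nuc_ind],
    stress = ind$stress[nuc_ind], wheel = ind$wheel[nuc_ind],
    dist_40d = ind$dist_40d[nuc_ind], dist_24h = ind$dist_24h[nuc_ind],
    dist_3h = ind$dist_3h[nuc_ind],
    dist_30_90m = ind$dist_30_90m[nuc_ind],
    dist_30m = ind$dist_30m[nuc_ind],
    stringsAsFactors = FALSE)

  genes_truth <- data.frame(
    gene = gene_ids, base_log_mean = base, theta = theta,
    marker_cluster = marker_of, mito = seq_len(G) %in% mito_idx,
    stringsAsFactors = FALSE)
  for (nm in intersect(names(te), c("stress", "wheel", "interaction",
                                    "distance"))) {
    col <- paste0("log2fc_", nm)
    genes_truth[[col]] <- 0
    gi <- resolve_genes(te[[nm]]$gene, gene_ids)
    genes_truth[[col]][gi] <- te[[nm]]$log2fc
  }
  nuclei_truth <- data.frame(
    barcode = barcode, individual = ind$individual[nuc_ind],
    group = ind$group[nuc_ind], cluster = cluster,
    maturity_rank = maturity_rank, planted_library = planted_lib,
    qc_violation = violation, stringsAsFactors = FALSE)

  list(counts = counts, meta = meta,
       truth = list(nuclei = nuclei_truth, genes = genes_truth,
                    individuals = ind),
       config = cfg)
}

#' Canned configuration for the planted-QC-violator fixture
#'
#' A [synth_config()] whose non-violator barcodes sit safely inside every
#' QC threshold (tight lognormal libraries around 3000 UMIs, no maturity
#' gradient, small individual effects), so that the only barcodes removed
#' by [apply_qc_filters()] are the planted violators and survivor counts
#' are exact arithmetic.
#'
#' @param n_nuclei total barcodes (default 100).
#' @param qc_violators violator counts as in [synth_config()] (default
#'   5 low-UMI, 3 low-gene, 2 high-UMI, 0 high-gene, 1 high-mito).
#' @param seed root seed.
#' @return a `synth_config`.
#' @export
qc_fixture_config <- function(n_nuclei = 100,
                              qc_violators = c(low_umi = 5, low_gene = 3,
                                               high_umi = 2, high_gene = 0,
                                               high_mito = 1),
                              seed = 1L) {
  synth_config(n_genes = 2000, n_nuclei = n_nuclei,
               n_individuals_per_group = 2,
               n_clusters = 1, marker_genes_per_cluster = 0,
               individual_sd = 0.1,
               library_logmean = log(3000), library_logsd = 0.25,
               mito_count_share = 0.008, dispersion_range = c(2, 10),
               maturity_gradient = FALSE,
               qc_violators = qc_violators, seed = seed)
}

#' Simulate a single negative-binomial gene with an individual random effect
#'
#' Gene-level simulator used by the differential-expression calibration
#' studies: counts for `n_individuals` x `nuclei_per_individual` nuclei are
#' drawn NB with mean `lib * exp(beta0 + beta1 * x_i + u_i)` where `x_i` is a
#' balanced 0/1 group indicator at the individual level and `u_i ~ N(0,
#' individual_sd^2)`.
#'
#' @param n_individuals number of individuals (split evenly into two groups).
#' @param nuclei_per_individual nuclei per individual.
#' @param beta0 baseline log mean relative expression (per unit library).
#' @param beta1 group log fold effect (natural log).
#' @param individual_sd SD of the individual random intercept.
#' @param theta NB size parameter.
#' @param library_logmean,library_logsd lognormal library sizes.
#' @return data.frame with columns y, individual, group, lib.
#' @export
simulate_nb_gene <- function(n_individuals = 12, nuclei_per_individual = 200,
                             beta0 = log(5e-4), beta1 = 0,
                             individual_sd = 0.5, theta = 2,
                             library_logmean = log(2000),
                             library_logsd = 0.45) {
  grp_i <- rep(c(0, 1), length.out = n_individuals)
  u <- rnorm(n_individuals, 0, individual_sd)
  n <- n_individuals * nuclei_per_individual
  indiv <- rep(seq_len(n_individuals), each = nuclei_per_individual)
  lib <- rlnorm(n, library_logmean, library_logsd)
  mu <- lib * exp(beta0 + beta1 * grp_i[indiv] + u[indiv])
  data.frame(y = rnbinom(n, mu = mu, size = theta),
             individual = factor(indiv), group = grp_i[indiv], lib = lib)
}

#' Simulate an individual-level cohort for mediation analysis
#'
#' Builds a per-individual table with a binary stress treatment, gene
#' expression columns and a 6-week running distance, with three planted gene
#' classes: mediator genes sit on the causal chain stress -> gene -> running
#' (`M = a0 + a T + e`, `Y = g0 + c' T + b M + e`), consequence genes respond
#' to running (`Y` first, then `M = a0 + b2 Y + e`), and null genes are
#' noise.
#'
#' @param n_per_group individuals per treatment arm.
#' @param a treatment -> mediator coefficient for mediator genes.
#' @param b mediator -> outcome coefficient for mediator genes.
#' @param cprime direct treatment -> outcome coefficient.
#' @param b2 outcome -> gene coefficient for consequence genes.
#' @param n_mediator,n_consequence,n_null gene counts per class.
#' @param noise_sd Gaussian noise SD for the mediator-gene equations.
#' @param noise_sd_outcome noise SD for the outcome equation (defaults to
#'   `noise_sd`).
#' @param noise_sd_consequence noise SD for the consequence-gene equations
#'   (defaults to `noise_sd`).
#' @return list with `data` (data.frame: individual, stress, dist_40d and one
#'   column per gene) and `truth` (data.frame: gene, class).
#' @export
simulate_mediation_cohort <- function(n_per_group = 12, a = 1, b = 0.5,
                                      cprime = 0, b2 = 0.5,
                                      n_mediator = 1, n_consequence = 1,
                                      n_null = 1, noise_sd = 0.1,
                                      noise_sd_outcome = noise_sd,
                                      noise_sd_consequence = noise_sd) {
  n <- 2 * n_per_group
  stress <- rep(c(0, 1), each = n_per_group)
  genes <- c(if (n_mediator) sprintf("med%02d", seq_len(n_mediator)),
             if (n_consequence) sprintf("cons%02d", seq_len(n_consequence)),
             if (n_null) sprintf("null%02d", seq_len(n_null)))
  cls <- c(rep("mediator", n_mediator), rep("consequence", n_consequence),
           rep("null", n_null))
  ## outcome built from the mediator chain (first mediator carries the chain;
  ## additional mediators are parallel chains contributing equally)
  med <- matrix(0, n, n_mediator)
  if (n_mediator > 0)
    for (j in seq_len(n_mediator))
      med[, j] <- a * stress + rnorm(n, 0, noise_sd)
  y <- cprime * stress + rnorm(n, 0, noise_sd_outcome)
  if (n_mediator > 0) y <- y + med %*% rep(b, n_mediator)
  y <- as.numeric(y)
  cons <- matrix(0, n, n_consequence)
  if (n_consequence > 0)
    for (j in seq_len(n_consequence))
      cons[, j] <- b2 * y + rnorm(n, 0, noise_sd_consequence)
  nul <- matrix(rnorm(n * n_null, 0, 1), n, n_null)
  dat <- data.frame(individual = sprintf("ind%02d", seq_len(n)),
                    stress = stress, dist_40d = y,
                    stringsAsFactors = FALSE)
  expr <- cbind(med, cons, nul)
  colnames(expr) <- genes
  list(data = cbind(dat, as.data.frame(expr)),
       truth = data.frame(gene = genes, class = cls,
                          stringsAsFactors = FALSE))
}
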