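#' Configuration for a synthetic expression cohort
#'
#' Defines a cohort with `n_normal` non-neoplastic mucosa samples and
#' `sum(group_sizes)` tumors split over `length(group_sizes)` planted
#' molecular subtypes. Expression is generated from a nonnegative metagene
#' model `A = W H` (one dominant metagene per tumor group), with planted
#' multiplicative fold changes and log-normal (log2-normal) multiplicative
#' noise. Defaults emulate a stage III colorectal cancer cohort of 101
#' tumors (group sizes 22/21/16/42) and 35 normals profiled on expression
#' arrays.
#'
#' Planted structure:
#' * a fraction `deg_fraction_vs_normal` of genes is differentially
#'   expressed in all tumors versus normal (half up by `fc_vs_normal`, half
#'   down by its reciprocal);
#' * a fraction `deg_fraction_vs_rest` of genes is split evenly into
#'   group-specific markers, up `fc_vs_rest`-fold in their own group versus
#'   the other groups *and* up `fc_vs_normal`-fold in tumors versus normal
#'   (subtype markers are tumor genes with subtype-specific amplification,
#'   which is what places them in the tumor-versus-normal DEG set that feeds
#'   consensus clustering).
#'
#' @param n_genes number of genes.
#' @param n_normal number of normal samples.
#' @param group_sizes integer vector of per-group tumor counts (each >= 2).
#' @param n_metagenes number of metagenes (default: number of groups).
#' @param deg_fraction_vs_normal fraction of genes planted as tumor-vs-normal
#'   DEGs, in (0,1).
#' @param deg_fraction_vs_rest fraction of genes planted as group markers
#'   (split across groups), in (0,1).
#' @param fc_vs_normal linear fold change (> 1) of tumor-vs-normal DEGs.
#' @param fc_vs_rest linear fold change (> 1) of a marker in its own group
#'   versus the other tumor groups.
#' @param noise_sd standard deviation of the multiplicative noise on the
#'   log2 scale.
#' @param baseline_log2_mean,baseline_log2_sd log2-normal distribution of
#'   baseline gene intensities.
#' @param hazards per-group event rate per month (length = number of groups).
#' @param censor_rate exponential censoring rate per month (>= 0).
#' @param max_followup_months administrative censoring time.
#' @param covariate_probs named list; each element a groups-by-categories
#'   probability matrix (rows sum to 1, colnames = category codes).
#' @param seed integer master seed; named sub-streams are derived per
#'   operation via [derive_seed()].
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_normal = 35,
                              group_sizes = c(22, 21, 16, 42),
                              n_metagenes = length(group_sizes),
                              deg_fraction_vs_normal = 0.15,
                              deg_fraction_vs_rest = 0.08,
                              fc_vs_normal = 3,
                              fc_vs_rest = 3,
                              noise_sd = 0.2,
                              baseline_log2_mean = 7,
                              baseline_log2_sd = 1,
                              hazards = c(0.004, 0.0002, 0.0008, 0.005),
                              censor_rate = 0.01,
                              max_followup_months = 115,
                              covariate_probs = default_covariate_probs(length(group_sizes)),
                              seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), n_normal = as.integer(n_normal),
              group_sizes = as.integer(group_sizes),
              n_metagenes = as.integer(n_metagenes),
              deg_fraction_vs_normal = deg_fraction_vs_normal,
              deg_fraction_vs_rest = deg_fraction_vs_rest,
              fc_vs_normal = fc_vs_normal, fc_vs_rest = fc_vs_rest,
              noise_sd = noise_sd,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              hazards = hazards, censor_rate = censor_rate,
              max_followup_months = max_followup_months,
              covariate_probs = covariate_probs, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Default group-dependent clinical covariate distributions
#'
#' Tumor location (right/left), MSI status and KRAS mutation probabilities
#' per group, patterned on the published group-wise frequencies of the
#' reference colorectal cohort (see [reference_clinical_counts()]). For
#' cohorts with a number of groups other than four, uniform two-category
#' covariates are returned.
#'
#' @param k number of tumor groups.
#' @return Named list of groups-by-categories probability matrices.
#' @export
default_covariate_probs <- function(k = 4) {
  if (k == 4) {
    list(
      location = matrix(c(.545, .455, .571, .429, .375, .625, .143, .857),
                        nrow = 4, byrow = TRUE,
                        dimnames = list(NULL, c("right", "left"))),
      msi = matrix(c(.909, .091, .714, .286, 1, 0, 1, 0), nrow = 4,
                   byrow = TRUE, dimnames = list(NULL, c("MSS", "MSI-high"))),
      kras = matrix(c(.364, .636, .714, .286, .437, .563, .738, .262),
                    nrow = 4, byrow = TRUE,
                    dimnames = list(NULL, c("wild", "mutant")))
    )
  } else {
    list(covariate1 = matrix(0.5, nrow = k, ncol = 2,
                             dimnames = list(NULL, c("a", "b"))))
  }
}

validate_simulation_config <- function(cfg) {
  k <- length(cfg$group_sizes)
  if (k < 2) stop("need at least 2 tumor groups (k_true >= 2)")
  if (any(cfg$group_sizes < 2)) stop("every group needs >= 2 samples")
  if (cfg$n_genes < 1 || cfg$n_normal < 0) stop("invalid cohort dimensions")
  if (cfg$n_metagenes < k) stop("n_metagenes must be >= number of groups")
  for (f in c("deg_fraction_vs_normal", "deg_fraction_vs_rest"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) stop(f, " must lie in (0,1)")
  if (round(cfg$deg_fraction_vs_normal * cfg$n_genes) < 1)
    stop("deg_fraction_vs_normal implies zero planted genes")
  if (floor(cfg$deg_fraction_vs_rest * cfg$n_genes / k) < 1)
    stop("deg_fraction_vs_rest implies zero planted markers per group")
  if (cfg$fc_vs_normal < 1 || cfg$fc_vs_rest < 1)
    stop("planted fold changes must be >= 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  if (length(cfg$hazards) != k) stop("need one hazard per group")
  if (any(cfg$hazards < 0) || cfg$censor_rate < 0)
    stop("hazards and censor_rate must be nonnegative")
  if (cfg$max_followup_months <= 0) stop("max_followup_months must be > 0")
  for (nm in names(cfg$covariate_probs)) {
    pm <- cfg$covariate_probs[[nm]]
    if (!is.matrix(pm) || nrow(pm) != k)
      stop("covariate_probs$", nm, " must be a ", k, "-row matrix")
    if (is.null(colnames(pm)))
      stop("covariate_probs$", nm, " needs category colnames")
    if (any(pm < 0) || any(abs(rowSums(pm) - 1) > 1e-9))
      stop("covariate_probs$", nm, " rows must be probabilities summing to 1")
  }
  invisible(cfg)
}

#' Simulate an expression cohort with planted subtypes
#'
#' Builds tumor expression as `A = W H` with nonnegative `W` (genes x
#' metagenes; a group's marker genes load `fc_vs_rest`-fold on its
#' metagene) and `H` (one dominant unit entry per tumor, off-group entries
#' small-uniform on (0, 0.04)), applies the planted tumor-versus-normal
#' multiplicative shifts, and multiplies log2-normal noise. All entries are
#' strictly positive. The same seed reproduces the cohort bit-identically.
#'
#' @param config a [simulation_config()].
#' @return A list with components
#'   \describe{
#'     \item{expression}{linear-scale [expr_matrix()], genes x samples;}
#'     \item{annotation}{data frame with `sample_id`, `tissue`, `group`
#'       (NA for normals);}
#'     \item{truth}{planted structure: `group` (named integer vector over
#'       tumor samples), `deg_up`, `deg_down` (tumor-vs-normal DEG gene
#'       ids; `deg_up` includes the markers), `markers` (list of gene ids
#'       per group).}
#'   }
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  k <- length(cfg$group_sizes)
  m <- cfg$n_metagenes
  n_tum <- sum(cfg$group_sizes)
  set.seed(derive_seed(cfg$seed, "cohort"))

  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  tumor_ids <- sprintf("T%03d", seq_len(n_tum))
  normal_ids <- if (cfg$n_normal > 0) sprintf("N%03d", seq_len(cfg$n_normal))
                else character(0)
  group <- rep(seq_len(k), cfg$group_sizes)

  # planted gene layout: [vs-normal up | vs-normal down | markers g1..gk | null]
  n_vn <- round(cfg$deg_fraction_vs_normal * cfg$n_genes)
  n_up <- ceiling(n_vn / 2); n_down <- n_vn - n_up
  n_per_group <- floor(cfg$deg_fraction_vs_rest * cfg$n_genes / k)
  idx_up <- seq_len(n_up)
  idx_down <- seq_len(n_down) + n_up
  idx_markers <- lapply(seq_len(k), function(g)
    n_vn + (g - 1) * n_per_group + seq_len(n_per_group))
  if (n_vn + k * n_per_group > cfg$n_genes)
    stop("planted DEG fractions exceed the gene count")

  mu <- 2^stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean,
                       cfg$baseline_log2_sd)

  # metagene loadings: baseline mu everywhere, markers boosted on own metagene
  W <- matrix(mu, nrow = cfg$n_genes, ncol = m)
  for (g in seq_len(k)) W[idx_markers[[g]], g] <- mu[idx_markers[[g]]] * cfg$fc_vs_rest

  # metagene expression per tumor: dominant own-group entry, small mixing
  H <- matrix(stats::runif(m * n_tum, 0, 0.04), nrow = m, ncol = n_tum)
  H[cbind(group, seq_len(n_tum))] <- 1

  A_tum <- W %*% H
  shift <- rep(1, cfg$n_genes)
  shift[idx_up] <- cfg$fc_vs_normal
  shift[idx_down] <- 1 / cfg$fc_vs_normal
  for (g in seq_len(k)) shift[idx_markers[[g]]] <- cfg$fc_vs_normal
  A_tum <- A_tum * shift

  A_norm <- matrix(mu, nrow = cfg$n_genes, ncol = cfg$n_normal)

  A <- cbind(A_tum, A_norm)
  if (cfg$noise_sd > 0)
    A <- A * 2^matrix(stats::rnorm(length(A), 0, cfg$noise_sd), nrow(A))
  dimnames(A) <- list(gene_ids, c(tumor_ids, normal_ids))

  annotation <- data.frame(
    sample_id = c(tumor_ids, normal_ids),
    tissue = c(rep("tumor", n_tum), rep("normal", cfg$n_normal)),
    group = c(group, rep(NA_integer_, cfg$n_normal)),
    stringsAsFactors = FALSE)

  truth <- list(
    group = stats::setNames(group, tumor_ids),
    deg_up = c(gene_ids[idx_up], unlist(lapply(idx_markers, function(i) gene_ids[i]))),
    deg_down = gene_ids[idx_down],
    markers = lapply(idx_markers, function(i) gene_ids[i]))

  list(expression = expr_matrix(A, scale = "linear"),
       annotation = annotation, truth = truth)
}

#' Simulate per-sample survival outcomes
#'
#' Event times are exponential with the sample's group hazard; follow-up is
#' cut by independent exponential censoring (`censor_rate`) and
#' administrative censoring at `max_followup_months`. The recorded time is
#' the minimum of the three; `event = 1` iff the event time came first.
#'
#' @param labels named integer vector (or factor) of group labels per sample.
#' @param config a [simulation_config()] supplying `hazards`, `censor_rate`,
#'   `max_followup_months` and `seed`.
#' @return Data frame with `sample_id`, `time_months`, `event`, `group`.
#' @export
simulate_survival <- function(labels, config) {
  validate_simulation_config(config)
  g <- as.integer(labels)
  k <- length(config$hazards)
  if (anyNA(g) || any(g < 1) || any(g > k))
    stop("unknown group label: no hazard defined")
  set.seed(derive_seed(config$seed, "survival"))
  n <- length(g)
  haz <- config$hazards[g]
  ev <- ifelse(haz > 0, stats::rexp(n, rate = pmax(haz, 1e-300)), Inf)
  cen <- if (config$censor_rate > 0) stats::rexp(n, rate = config$censor_rate)
         else rep(Inf, n)
  time <- pmin(ev, cen, config$max_followup_months)
  event <- as.integer(ev <= pmin(cen, config$max_followup_months))
  data.frame(sample_id = if (is.null(names(labels)))
               sprintf("S%03d", seq_len(n)) else names(labels),
             time_months = time, event = event, group = g,
             stringsAsFactors = FALSE)
}

#' Simulate group-dependent categorical clinical covariates
#'
#' Each covariate is drawn i.i.d. from its group's categorical distribution
#' in `config$covariate_probs`.
#'
#' @inheritParams simulate_survival
#' @return Data frame: `sample_id`, `group`, one character column per
#'   covariate (category codes).
#' @export
simulate_clinical <- function(labels, config) {
  validate_simulation_config(config)
  g <- as.integer(labels)
  k <- length(config$group_sizes)
  if (anyNA(g) || any(g < 1) || any(g > k)) stop("unknown group label")
  set.seed(derive_seed(config$seed, "clinical"))
  out <- data.frame(sample_id = if (is.null(names(labels)))
                      sprintf("S%03d", seq_along(g)) else names(labels),
                    group = g, stringsAsFactors = FALSE)
  for (nm in names(config$covariate_probs)) {
    pm <- config$covariate_probs[[nm]]
    cats <- colnames(pm)
    out[[nm]] <- vapply(g, function(gi)
      sample(cats, 1L, prob = pm[gi, ]), character(1))
  }
  out
}
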