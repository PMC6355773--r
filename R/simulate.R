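#' Simulation configuration for a matched cohort
#'
#' Describes a synthetic cohort of matched expression, RPPA and clinical
#' data with known planted structure.  Each protein marker has a latent
#' per-sample activation variable that drives (a) the marker's RPPA
#' value (latent plus Gaussian noise), (b) planted signature genes whose
#' log2 expression shifts with the latent so that the mean difference
#' between activated and inactivated samples is \code{effect_size}
#' (+ for up genes, - for down genes), (c) subtype assignment through a
#' logistic model, (d) mutation flags through a logistic model on the
#' latent, and (e) exponential survival with hazard proportional to
#' \code{exp(sum(log_hr * standardized latent))}.
#'
#' Defaults mirror a luminal breast-cancer cohort: two markers
#' (\code{pAKT}, \code{pmTOR}) with disjoint planted gene sets, pAKT
#' activation enriched in luminal A and protective (hazard ratio below
#' 1), p-mTOR activation enriched in luminal B and deleterious.
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes; planted sets are drawn from the
#'   front of the gene list, disjoint across markers.
#' @param markers character vector of marker names.
#' @param planted_up,planted_down planted gene counts per marker
#'   (recycled across markers).
#' @param effect_size mean log2 expression shift between activated and
#'   inactivated samples for planted genes.
#' @param marker_noise_sd standard deviation of Gaussian measurement
#'   noise added to the unit-variance latent to give the RPPA value.
#' @param prop_lumB approximate marginal proportion of luminal B.
#' @param subtype_score_shift per-marker log-odds of luminal B per unit
#'   latent activation (negative = marker associated with luminal A).
#' @param mutation_model named list per mutation gene with elements
#'   \code{marker}, \code{intercept} (log-odds) and \code{beta}
#'   (log-odds per unit latent).
#' @param survival_model list with \code{baseline} (events per month),
#'   \code{log_hr} (named, per SD of latent activation) and
#'   \code{censor_rate} in [0, 1).
#' @param seed integer seed for the cohort's single RNG stream.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 300L, n_genes = 5000L,
                       markers = c("pAKT", "pmTOR"),
                       planted_up = 40L, planted_down = 40L,
                       effect_size = 1.5, marker_noise_sd = 0.5,
                       prop_lumB = 0.37,
                       subtype_score_shift = c(pAKT = -1, pmTOR = 1),
                       mutation_model = list(
                         PIK3CA = list(marker = "pAKT",
                                       intercept = stats::qlogis(0.35),
                                       beta = 1),
                         P53 = list(marker = "pmTOR",
                                    intercept = stats::qlogis(0.20),
                                    beta = 1)),
                       survival_model = list(
                         baseline = 0.005,
                         log_hr = c(pAKT = log(0.79), pmTOR = log(1.1)),
                         censor_rate = 0.7),
                       seed = 1L) {
  markers <- as.character(markers)
  planted_up <- rep_len(as.integer(planted_up), length(markers))
  planted_down <- rep_len(as.integer(planted_down), length(markers))
  if (sum(planted_up) + sum(planted_down) > n_genes)
    stop("planted gene counts exceed n_genes")
  if (prop_lumB < 0 || prop_lumB > 1) stop("prop_lumB must lie in [0, 1]")
  cr <- survival_model$censor_rate
  if (is.null(cr) || cr < 0 || cr >= 1)
    stop("survival_model$censor_rate must lie in [0, 1)")
  subtype_score_shift <- rep_len(subtype_score_shift, length(markers))
  names(subtype_score_shift) <- markers
  lh <- rep_len(survival_model$log_hr, length(markers))
  names(lh) <- markers
  survival_model$log_hr <- lh
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes), markers = markers,
                 planted_up = planted_up, planted_down = planted_down,
                 effect_size = effect_size,
                 marker_noise_sd = marker_noise_sd,
                 prop_lumB = prop_lumB,
                 subtype_score_shift = subtype_score_shift,
                 mutation_model = mutation_model,
                 survival_model = survival_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Top-level keys are passed to [sim_config()] as arguments.
#'
#' @param path YAML file path.
#' @return a \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  do.call(sim_config, yaml::read_yaml(path))
}

# mean shift between activated (latent > 0) and inactivated halves of a
# standard normal latent is coef * 2*sqrt(2/pi); invert to get the
# coefficient that realises effect_size
.effect_coef <- function(effect_size) effect_size / (2 * sqrt(2 / pi))

#' Simulate a matched expression / RPPA / clinical cohort
#'
#' Deterministic given \code{config$seed}: one RNG stream drives the
#' whole cohort.  The planted truth (gene sets, latent activations,
#' generating parameters) is returned alongside the data so downstream
#' stages can be tested for parameter recovery.
#'
#' @param config a [sim_config()].
#' @return list of class \code{sim_cohort} with elements \code{expr}
#'   (expression matrix), \code{rppa} (RPPA table), \code{clinical}
#'   (clinical table) and \code{truth} (list: \code{planted} gene sets
#'   per marker, \code{latent} n x markers matrix, \code{config}).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  g <- config$n_genes
  mk <- config$markers
  samples <- sprintf("S%04d", seq_len(n))
  genes <- sprintf("g%05d", seq_len(g))

  latent <- matrix(stats::rnorm(n * length(mk)), n, length(mk),
                   dimnames = list(samples, mk))
  rppa <- latent + matrix(stats::rnorm(n * length(mk), 0,
                                       config$marker_noise_sd),
                          n, length(mk))
  dimnames(rppa) <- list(samples, mk)

  expr <- matrix(stats::rnorm(g * n), g, n, dimnames = list(genes, samples))
  coef <- .effect_coef(config$effect_size)
  planted <- list()
  nxt <- 1L
  for (i in seq_along(mk)) {
    up <- genes[seq.int(nxt, length.out = config$planted_up[i])]
    nxt <- nxt + config$planted_up[i]
    dn <- genes[seq.int(nxt, length.out = config$planted_down[i])]
    nxt <- nxt + config$planted_down[i]
    planted[[mk[i]]] <- list(up = up, down = dn)
    expr[up, ] <- expr[up, ] + rep(coef * latent[, i], each = length(up))
    expr[dn, ] <- expr[dn, ] - rep(coef * latent[, i], each = length(dn))
  }

  lp <- stats::qlogis(config$prop_lumB) +
    as.vector(latent %*% config$subtype_score_shift)
  subtype <- ifelse(stats::runif(n) < stats::plogis(lp), "LumB", "LumA")

  clin <- data.frame(sample_id = samples, subtype = subtype,
                     age = round(pmin(pmax(stats::rnorm(n, 58, 10), 25), 90)),
                     size = round(stats::rlnorm(n, log(20), 0.5)),
                     grade = sample(1:3, n, replace = TRUE,
                                    prob = c(0.2, 0.5, 0.3)),
                     nodal_status = stats::rbinom(n, 1, 0.35),
                     endocrine_only = stats::rbinom(n, 1, 0.5),
                     stringsAsFactors = FALSE)

  mut <- config$mutation_model
  if (!is.null(mut$PIK3CA)) {
    a <- latent[, mut$PIK3CA$marker]
    carrier <- stats::rbinom(n, 1,
                             stats::plogis(mut$PIK3CA$intercept +
                                             mut$PIK3CA$beta * a)) == 1
    exon <- rep("wt", n)
    # kinase-domain hotspots (exon 20) are the most frequent class in
    # luminal disease, then helical-domain exon 9
    exon[carrier] <- sample(c("exon9", "exon20", "other_exon"),
                            sum(carrier), replace = TRUE,
                            prob = c(0.30, 0.45, 0.25))
    clin$pik3ca_status <- exon
  }
  if (!is.null(mut$P53)) {
    a <- latent[, mut$P53$marker]
    clin$p53_status <- ifelse(
      stats::rbinom(n, 1, stats::plogis(mut$P53$intercept +
                                          mut$P53$beta * a)) == 1,
      "mut", "wt")
  }

  sv <- config$survival_model
  z <- scale(latent)
  haz <- sv$baseline * exp(as.vector(z %*% sv$log_hr))
  surv <- .censored_exponential(haz, sv$censor_rate)
  clin$rfs_time <- surv$time
  clin$rfs_event <- surv$event

  structure(list(
    expr = expression_matrix(expr, dataset_id = paste0("sim", config$seed)),
    rppa = rppa_table(rppa),
    clinical = clinical_table(clin),
    truth = list(planted = planted, latent = latent, config = config)),
    class = "sim_cohort")
}

# draw exponential event times with per-sample hazards plus an
# independent exponential censor whose rate is tuned so the expected
# fraction censored matches censor_rate
.censored_exponential <- function(hazard, censor_rate) {
  n <- length(hazard)
  t_event <- stats::rexp(n, rate = hazard)
  if (censor_rate <= 0) {
    return(list(time = t_event, event = rep(1L, n)))
  }
  f <- function(lc) mean(lc / (lc + hazard)) - censor_rate
  lc <- stats::uniroot(f, lower = 1e-10, upper = max(hazard) * 1e4,
                       tol = 1e-12)$root
  t_cens <- stats::rexp(n, rate = lc)
  list(time = pmin(t_event, t_cens),
       event = as.integer(t_event <= t_cens))
}

#' Simulate survival times from a proportional-hazards model on a score
#'
#' Event times are exponential with hazard
#' \code{baseline * exp(log_hr * z(score))} where \code{z} standardizes
#' the score; censoring is an independent exponential whose rate is
#' chosen so the expected censored fraction is \code{censor_rate}.
#'
#' @param scores per-sample numeric scores (finite).
#' @param log_hr log hazard ratio per SD of score.
#' @param baseline baseline hazard (events per time unit).
#' @param censor_rate target censored fraction in [0, 1).
#' @param seed optional integer seed.
#' @return data.frame with \code{rfs_time} and \code{rfs_event}.
#' @export
simulate_survival <- function(scores, log_hr, baseline = 0.005,
                              censor_rate = 0.3, seed = NULL) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  z <- if (stats::sd(scores) > 0) as.vector(scale(scores)) else scores * 0
  haz <- baseline * exp(log_hr * z)
  s <- .censored_exponential(haz, censor_rate)
  data.frame(rfs_time = s$time, rfs_event = s$event)
}

#' Write a simulated cohort to tab-delimited files
#'
#' Writes \code{expression.tsv}, \code{rppa.tsv}, \code{clinical.tsv}
#' and \code{truth.json} (planted gene sets) under \code{dir}.
#'
#' @param cohort a \code{sim_cohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_matrix(cohort$expr, file.path(dir, "expression.tsv"), "gene_id")
  write_tsv_matrix(cohort$rppa, file.path(dir, "rppa.tsv"), "sample_id")
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(cohort$truth$planted,
                         file.path(dir, "truth.json"))
  }
  invisible(dir)
}
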