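#' Specify a genotype failure model
#'
#' A failure model describes how de novo methylation behaves for one genotype.
#' Four kinds are supported, mirroring the competing hypotheses for a weak
#' methylation phenotype:
#' \describe{
#'   \item{wildtype}{every locus is methylated at `mu_hi`.}
#'   \item{uniform_inefficiency}{every eligible locus is methylated at
#'     `efficiency_f * mu_hi` (the process works everywhere, but less well).}
#'   \item{deterministic}{a fixed subset of eligible loci (fraction
#'     `failed_fraction_q`, identical in every replicate) is methylated at
#'     `mu_lo`; the rest at `mu_hi`.}
#'   \item{stochastic}{each eligible locus fails independently in each
#'     replicate with probability `failure_prob_p`, dropping to `mu_lo`.}
#' }
#' Only loci with divergence at or below `divergence_max` are eligible to be
#' affected ("young" elements); older loci behave as wildtype under every
#' model.
#'
#' @param kind One of `"wildtype"`, `"uniform_inefficiency"`,
#'   `"deterministic"`, `"stochastic"`.
#' @param mu_hi True methylation fraction of unaffected loci, in \[0, 1\].
#' @param mu_lo True methylation fraction of failed loci, in \[0, 1\];
#'   must not exceed `mu_hi`.
#' @param efficiency_f Multiplicative efficiency in (0, 1\]
#'   (uniform_inefficiency only).
#' @param failed_fraction_q Fraction of eligible loci in the fixed failed
#'   subset (deterministic only).
#' @param failure_prob_p Per-locus, per-replicate failure probability
#'   (stochastic only).
#' @param divergence_max Eligibility ceiling in percent divergence; loci more
#'   diverged than this are never affected. Default `Inf`.
#' @return An object of class `failure_model`.
#' @export
failure_model <- function(kind = c("wildtype", "uniform_inefficiency",
                                   "deterministic", "stochastic"),
                          mu_hi = 0.85, mu_lo = 0,
                          efficiency_f = NULL, failed_fraction_q = NULL,
                          failure_prob_p = NULL, divergence_max = Inf) {
  kind <- match.arg(kind)
  stopifnot(mu_hi >= 0, mu_hi <= 1, mu_lo >= 0, mu_lo <= 1, mu_lo <= mu_hi,
            divergence_max >= 0)
  if (kind == "uniform_inefficiency") {
    if (is.null(efficiency_f)) stop("uniform_inefficiency requires efficiency_f")
    stopifnot(efficiency_f > 0, efficiency_f <= 1)
  } else if (!is.null(efficiency_f)) {
    stop("efficiency_f is only meaningful for kind = 'uniform_inefficiency'")
  }
  if (kind == "deterministic") {
    if (is.null(failed_fraction_q)) stop("deterministic requires failed_fraction_q")
    stopifnot(failed_fraction_q >= 0, failed_fraction_q <= 1)
  } else if (!is.null(failed_fraction_q)) {
    stop("failed_fraction_q is only meaningful for kind = 'deterministic'")
  }
  if (kind == "stochastic") {
    if (is.null(failure_prob_p)) stop("stochastic requires failure_prob_p")
    stopifnot(failure_prob_p >= 0, failure_prob_p <= 1)
  } else if (!is.null(failure_prob_p)) {
    stop("failure_prob_p is only meaningful for kind = 'stochastic'")
  }
  structure(list(kind = kind, mu_hi = mu_hi, mu_lo = mu_lo,
                 efficiency_f = efficiency_f,
                 failed_fraction_q = failed_fraction_q,
                 failure_prob_p = failure_prob_p,
                 divergence_max = divergence_max),
            class = "failure_model")
}

#' Simulation configuration for the synthetic methylome
#'
#' @param families Data frame with one row per transposon family: `name`,
#'   `n_loci`, `div_mean` and `div_sd` (normal divergence distribution,
#'   truncated at 0), `consensus_length` (bp).
#' @param cpgs_per_locus Number of CpG dyads per locus.
#' @param coverage_lambda Mean per-CpG read depth (Poisson).
#' @param n_replicates Biological replicates per genotype (>= 2).
#' @param seed Master seed; all replicate substreams derive from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(families, cpgs_per_locus = 20L, coverage_lambda = 50,
                       n_replicates = 3L, seed = 1L) {
  families <- tibble::as_tibble(families)
  stopifnot(all(c("name", "n_loci", "div_mean", "div_sd", "consensus_length")
                %in% names(families)),
            all(families$n_loci >= 0), coverage_lambda > 0,
            n_replicates >= 2, cpgs_per_locus >= 1)
  structure(list(families = families,
                 cpgs_per_locus = as.integer(cpgs_per_locus),
                 coverage_lambda = coverage_lambda,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic substream seed below 2^31, from the master seed and a label.
substream_seed <- function(master, ...) {
  label <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a transposon locus annotation
#'
#' Places non-overlapping full-length loci on a synthetic chromosome
#' (`chrSim`), drawing per-locus divergence from each family's truncated
#' normal distribution. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A locus annotation tibble (see [read_annotation()]).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "annotation"), {
    fam <- config$families
    rows <- vector("list", nrow(fam))
    cursor <- 1000L
    counter <- 0L
    for (i in seq_len(nrow(fam))) {
      n <- fam$n_loci[i]
      if (n == 0L) {
        rows[[i]] <- NULL
        next
      }
      len <- as.integer(fam$consensus_length[i])
      div <- abs(stats::rnorm(n, fam$div_mean[i], fam$div_sd[i]))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      starts <- cursor + cumsum(c(0L, rep(len + 5000L, n - 1L)))
      cursor <- starts[n] + len + 5000L
      rows[[i]] <- tibble::tibble(
        locus_id = sprintf("%s_%04d", fam$name[i], seq_len(n) + counter),
        chrom = "chrSim", start = as.integer(starts),
        end = as.integer(starts + len), strand = strand,
        family = fam$name[i], divergence = div,
        consensus_length = len
      )
      counter <- counter + n
    }
    dplyr::bind_rows(rows)
  })
}

# True methylation level per locus for one replicate under a failure model.
# The deterministic failed subset depends only on (master seed, genotype),
# never on the replicate, so it is identical across replicates.
locus_true_levels <- function(annotation, model, config, genotype, replicate_index) {
  eligible <- annotation$divergence <= model$divergence_max
  m <- rep(model$mu_hi, nrow(annotation))
  failed <- rep(FALSE, nrow(annotation))
  if (model$kind == "uniform_inefficiency") {
    m[eligible] <- model$efficiency_f * model$mu_hi
    failed <- eligible & model$efficiency_f < 1
  } else if (model$kind == "deterministic") {
    idx <- which(eligible)
    n_fail <- round(model$failed_fraction_q * length(idx))
    fail_idx <- with_seed(substream_seed(config$seed, "fates", genotype),
                          sample(idx, n_fail))
    m[fail_idx] <- model$mu_lo
    failed[fail_idx] <- TRUE
  } else if (model$kind == "stochastic") {
    draw <- with_seed(
      substream_seed(config$seed, "fates", genotype, replicate_index),
      stats::runif(nrow(annotation))
    )
    hit <- eligible & draw < model$failure_prob_p
    m[hit] <- model$mu_lo
    failed[hit] <- TRUE
  }
  tibble::tibble(locus_id = annotation$locus_id, true_m = m,
                 failed = failed, eligible = eligible)
}

# Evenly spaced CpG dyad positions (1-based position of the + strand C).
locus_cpg_positions <- function(start, end, n_cpg) {
  len <- end - start
  offs <- floor((seq_len(n_cpg) - 0.5) / n_cpg * (len - 1L))
  start + 1L + as.integer(offs)
}

#' Simulate one replicate's cytosine report
#'
#' Per locus, the failure model sets a true methylation fraction; each CpG
#' dyad then receives independent Poisson coverage on each strand (mean
#' `coverage_lambda / 2` per strand) and Binomial methylated calls. Both
#' strands of every CpG are emitted as separate cytosine lines, so the
#' downstream strand merge is exercised.
#'
#' @param annotation Locus annotation tibble.
#' @param model A [failure_model()].
#' @param config A [sim_config()].
#' @param replicate_index Replicate number (1-based).
#' @param genotype Genotype label used in seed derivation.
#' @return A list with `records` (cytosine report tibble) and `truth`
#'   (per-locus tibble: `locus_id`, `genotype`, `replicate`, `true_m`,
#'   `failed`, `eligible`).
#' @export
simulate_replicate <- function(annotation, model, config, replicate_index,
                               genotype = "sample") {
  stopifnot(inherits(model, "failure_model"), inherits(config, "sim_config"))
  truth <- locus_true_levels(annotation, model, config, genotype, replicate_index)
  n_cpg <- config$cpgs_per_locus
  with_seed(substream_seed(config$seed, "reads", genotype, replicate_index), {
    n_loci <- nrow(annotation)
    pos <- unlist(lapply(seq_len(n_loci), function(i) {
      locus_cpg_positions(annotation$start[i], annotation$end[i], n_cpg)
    }))
    m <- rep(truth$true_m, each = n_cpg)
    total <- n_loci * n_cpg
    cov_plus <- stats::rpois(total, config$coverage_lambda / 2)
    cov_minus <- stats::rpois(total, config$coverage_lambda / 2)
    meth_plus <- stats::rbinom(total, cov_plus, m)
    meth_minus <- stats::rbinom(total, cov_minus, m)
    records <- tibble::tibble(
      chrom = rep(annotation$chrom, each = 2L * n_cpg),
      pos = as.integer(c(rbind(pos, pos + 1L))),
      strand = rep(c("+", "-"), times = total),
      n_meth = as.integer(c(rbind(meth_plus, meth_minus))),
      n_unmeth = as.integer(c(rbind(cov_plus - meth_plus,
                                    cov_minus - meth_minus))),
      context = "CpG",
      trinucleotide = rep(c("CGA", "CGT"), times = total)
    )
    list(records = records,
         truth = tibble::tibble(locus_id = truth$locus_id, genotype = genotype,
                                replicate = replicate_index,
                                true_m = truth$true_m, failed = truth$failed,
                                eligible = truth$eligible))
  })
}

#' Simulate a multi-genotype cohort of cytosine reports
#'
#' @param annotation Locus annotation tibble.
#' @param models Named list of [failure_model()] objects, one per genotype.
#' @param config A [sim_config()].
#' @return A list with `reports` (nested list `reports[[genotype]][[rep]]` of
#'   cytosine report tibbles) and `truth` (row-bound per-locus ground truth).
#' @export
simulate_cohort <- function(annotation, models, config) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  reports <- list()
  truths <- list()
  for (g in names(models)) {
    reports[[g]] <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      sim <- simulate_replicate(annotation, models[[g]], config, r, g)
      reports[[g]][[r]] <- sim$records
      truths[[paste(g, r)]] <- sim$truth
    }
  }
  list(reports = reports, truth = dplyr::bind_rows(truths))
}

#' Simulate a locus methylation matrix directly
#'
#' Locus-level shortcut that is distribution-identical to simulating the full
#' cytosine report and pooling counts: total locus coverage is
#' Poisson(`coverage_lambda * cpgs_per_locus`) (the sum of the per-CpG
#' per-strand Poisson depths) and methylated calls are Binomial at the true
#' locus level. Used where many cohorts are needed (power studies).
#'
#' @inheritParams simulate_cohort
#' @return A long locus methylation matrix tibble (see
#'   [build_locus_matrix()]), plus ground-truth columns `true_m` and `failed`.
#' @export
simulate_locus_matrix <- function(annotation, models, config) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  out <- list()
  for (g in names(models)) {
    for (r in seq_len(config$n_replicates)) {
      truth <- locus_true_levels(annotation, models[[g]], config, g, r)
      vals <- with_seed(substream_seed(config$seed, "reads", g, r), {
        cov <- stats::rpois(nrow(annotation),
                            config$coverage_lambda * config$cpgs_per_locus)
        meth <- stats::rbinom(nrow(annotation), cov, truth$true_m)
        ifelse(cov > 0, 100 * meth / cov, NA_real_)
      })
      out[[paste(g, r)]] <- tibble::tibble(
        locus_id = annotation$locus_id, family = annotation$family,
        divergence = annotation$divergence, genotype = g, replicate = r,
        meth = vals, true_m = truth$true_m, failed = truth$failed
      )
    }
  }
  dplyr::bind_rows(out)
}
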