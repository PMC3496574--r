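#' Simulate a DMET-format case-control genotype dataset
#'
#' Generates a probes-by-samples genotype table with known structure for
#' benchmarking the association scan. Each probe is bi-allelic: two alleles
#' are drawn from \{A, C, G, T\}, a minor-allele frequency is drawn
#' uniformly from `maf_range`, and the three genotype probabilities follow
#' Hardy-Weinberg proportions. Null probes use that distribution in both
#' classes. Associated probes shift genotype mass between the classes: with
#' separation `s`, class A mixes the base distribution with a point mass on
#' one homozygote and class B with the other, `(1-s) d0 + s 1{hom}`, so
#' `s = 1` gives complete separation. Every call is independently replaced
#' by `NoCall` with probability `nocall_rate`. Generation is reproducible:
#' each probe draws from its own stream, seeded as a fixed function of
#' `seed` and the probe index, so the same arguments always give the same
#' dataset.
#'
#' @param m_null Number of null probes (default 1936, the DMET chip's
#'   marker count, with no associated probes).
#' @param m_assoc Number of associated probes.
#' @param n_a,n_b Samples per class (classes are named `"A"` and `"B"`).
#' @param separation Effect size in \[0, 1\] for associated probes; 1 =
#'   complete separation.
#' @param assoc_dists Optional explicit effect specification overriding
#'   `separation`: a list of `list(dist_a = , dist_b = )` pairs of named
#'   genotype probability vectors, recycled across associated probes. Each
#'   distribution must sum to 1 (tolerance 1e-9).
#' @param nocall_rate Per-cell NoCall probability in \[0, 1).
#' @param maf_range Range of the per-probe minor-allele frequency.
#' @param seed Integer seed; same inputs, same output, bit for bit.
#' @return A list with `dataset` (a [dmet_dataset]) and `truth` (tibble
#'   `probe_id`, `is_associated`, `dist_a`, `dist_b`, distributions as JSON
#'   strings), plus the `seed` and `nocall_rate` used.
#' @examples
#' sim <- simulate_dmet(m_null = 50, m_assoc = 2, n_a = 5, n_b = 5, seed = 1)
#' sim$dataset
#' @export
simulate_dmet <- function(m_null = 1936, m_assoc = 0, n_a = 10, n_b = 10,
                          separation = 1, assoc_dists = NULL,
                          nocall_rate = 0, maf_range = c(0.05, 0.5),
                          seed = 1) {
  if (m_null + m_assoc < 1) {
    abort("Need at least one probe.", class = "dmetr_validation_error")
  }
  if (n_a < 1 || n_b < 1) {
    abort("Both class sizes must be >= 1.", class = "dmetr_validation_error")
  }
  if (!is.numeric(nocall_rate) || nocall_rate < 0 || nocall_rate >= 1) {
    abort("`nocall_rate` must lie in [0, 1).", class = "dmetr_validation_error")
  }
  if (!is.numeric(separation) || separation < 0 || separation > 1) {
    abort("`separation` must lie in [0, 1].", class = "dmetr_validation_error")
  }
  m <- m_null + m_assoc
  ids <- sprintf("probe_%05d", seq_len(m))
  is_assoc <- c(rep(FALSE, m_null), rep(TRUE, m_assoc))
  samples <- c(sprintf("A_%03d", seq_len(n_a)), sprintf("B_%03d", seq_len(n_b)))
  classes <- stats::setNames(rep(c("A", "B"), c(n_a, n_b)), samples)

  if (!is.null(assoc_dists)) {
    for (ad in assoc_dists) validate_dist_pair(ad)
  }

  calls <- matrix(NA_character_, m, n_a + n_b,
                  dimnames = list(ids, samples))
  dist_a_json <- dist_b_json <- character(m)
  for (i in seq_len(m)) {
    set.seed(probe_seed(seed, i))
    alleles <- sort(sample(c("A", "C", "G", "T"), 2),
                    method = "radix")
    syms <- c(paste0(alleles[1], "/", alleles[1]),
              paste0(alleles[1], "/", alleles[2]),
              paste0(alleles[2], "/", alleles[2]))
    maf <- runif(1, maf_range[1], maf_range[2])
    d0 <- stats::setNames(c((1 - maf)^2, 2 * maf * (1 - maf), maf^2), syms)
    if (is_assoc[i]) {
      if (!is.null(assoc_dists)) {
        ad <- assoc_dists[[(i - m_null - 1) %% length(assoc_dists) + 1]]
        da <- ad$dist_a
        db <- ad$dist_b
      } else {
        point_a <- stats::setNames(c(1, 0, 0), syms)
        point_b <- stats::setNames(c(0, 0, 1), syms)
        da <- (1 - separation) * d0 + separation * point_a
        db <- (1 - separation) * d0 + separation * point_b
      }
    } else {
      da <- db <- d0
    }
    g <- c(
      sample(names(da), n_a, replace = TRUE, prob = da),
      sample(names(db), n_b, replace = TRUE, prob = db)
    )
    if (nocall_rate > 0) {
      g[runif(n_a + n_b) < nocall_rate] <- nocall_token
    }
    calls[i, ] <- g
    dist_a_json[i] <- dist_json(da)
    dist_b_json[i] <- dist_json(db)
  }

  truth <- tibble::tibble(
    probe_id = ids,
    is_associated = dist_a_json != dist_b_json,
    dist_a = dist_a_json,
    dist_b = dist_b_json
  )
  list(dataset = dmet_dataset(calls, classes), truth = truth,
       seed = seed, nocall_rate = nocall_rate)
}

#' Null-dataset series over increasing cohort sizes
#'
#' One all-null dataset per requested total sample count (split as evenly
#' as possible between the two classes), each generated deterministically
#' from `seed` and its size. Used by the scalability benchmark.
#'
#' @param sizes Vector of total sample counts, all positive.
#' @param probes Probes per dataset.
#' @param seed Integer seed.
#' @return A named list of [dmet_dataset] objects, names `n<size>`.
#' @export
simulate_scale_series <- function(sizes, probes = 1936, seed = 1) {
  if (!length(sizes)) {
    abort("`sizes` must be non-empty.", class = "dmetr_validation_error")
  }
  if (any(sizes < 1)) {
    abort("All sizes must be positive.", class = "dmetr_validation_error")
  }
  out <- lapply(sizes, function(s) {
    simulate_dmet(m_null = probes, m_assoc = 0,
                  n_a = ceiling(s / 2), n_b = floor(max(s / 2, 1)),
                  nocall_rate = 0,
                  seed = (seed + 7919 * s) %% 2147483647)$dataset
  })
  stats::setNames(out, paste0("n", sizes))
}

probe_seed <- function(seed, i) {
  (abs(seed) + 1000003 * i) %% 2147483647
}

dist_json <- function(d) {
  d <- d[d > 0]
  as.character(jsonlite::toJSON(as.list(d), auto_unbox = TRUE, digits = NA))
}

validate_dist_pair <- function(ad) {
  for (nm in c("dist_a", "dist_b")) {
    d <- ad[[nm]]
    if (is.null(d) || is.null(names(d)) ||
        abs(sum(d) - 1) > 1e-9 || any(d < 0)) {
      abort(sprintf("`assoc_dists` entry `%s` must be a named non-negative vector summing to 1.", nm),
            class = "dmetr_validation_error")
    }
  }
  invisible(TRUE)
}
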