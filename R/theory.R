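#' Expected IBD sharing between relatives
#'
#' Closed-form expectations for the number and total length of IBD segments
#' between a pair of relatives separated by `m` meioses through `a` shared
#' ancestors (a = 1 for half relationships, 2 for full). At any genomic
#' point the pair is IBD through a given shared ancestor with probability
#' `2^(1-m)`; IBD runs end at a crossover in any of the `m` meioses, so run
#' lengths are exponential with rate `m` per Morgan, truncated at
#' chromosome ends. On a chromosome of length `l`, with a detection
#' threshold `t = min_len` (Morgans), stationarity of the run process gives
#'
#' * run starts: density `a * m * 2^(1-m)` per Morgan in the interior, plus
#'   probability `a * 2^(1-m)` of starting in the IBD state at the
#'   chromosome start;
#' * expected count of runs of length at least `t`:
#'   `a * 2^(1-m) * exp(-m t) * (m (l - t) + 1)`;
#' * expected total length of such runs, accounting for truncation of the
#'   exponential at the chromosome end.
#'
#' Summed over chromosomes and with `l` much longer than `1/m` this reduces
#' to the familiar `a * 2^(1-m) * (m L + C) * exp(-m t)` segments of mean
#' excess length `1/m`. Detected pairs are ascertained on having at least
#' one segment; treating the count as Poisson, the conditional expectations
#' divide by `1 - exp(-E[n])`. The forward gene-dropping oracle
#' ([relative_pair_ibd()]) is the arbiter for these formulas.
#'
#' @param m total meioses separating the pair through the shared
#'   ancestor(s); at least 2 (2 = siblings, 4 = first cousins, ...).
#' @param a number of shared ancestors, 1 or 2.
#' @param map a [genetic_map()].
#' @param min_len detection threshold in Morgans (e.g. 0.05 for 5 cM).
#' @return A one-row tibble per `m`: unconditional `expected_n` /
#'   `expected_total_cm`, detection probability `p_detected`, and the
#'   detection-conditioned `expected_n_detected` / `expected_total_cm_detected`.
#' @examples
#' expected_ibd(m = 4, a = 2, map = human22_map(), min_len = 0.05) # 1st cousins
#' @export
expected_ibd <- function(m, a, map, min_len = 0) {
  if (any(m < 2)) stop("`m` must be at least 2 meioses", call. = FALSE)
  stopifnot(all(a %in% c(1, 2)), min_len >= 0, inherits(map, "genetic_map"))
  one <- function(m, a) {
    t <- min_len
    pi0 <- a * 2^(1 - m)          # point IBD probability
    rho <- m * pi0                # interior run-start density per Morgan
    cnt <- 0
    len <- 0
    for (l in map$lengths) {
      if (t >= l) next
      cnt <- cnt + pi0 * exp(-m * t) * (m * (l - t) + 1)
      # E[min(Exp(m), A) ; run >= t] for a run with A Morgans available
      elen <- function(A) t * exp(-m * t) + (exp(-m * t) - exp(-m * A)) / m
      # interior starts: available length A = l - u, u ~ Uniform(0, l - t)
      len <- len + rho * ((l - t) * (t + 1 / m) * exp(-m * t) -
                            (exp(-m * t) - exp(-m * l)) / m^2)
      # run already IBD at the chromosome start
      len <- len + pi0 * elen(l)
    }
    c(cnt, len)
  }
  res <- mapply(one, m, a)
  en <- res[1, ]
  elen <- res[2, ]
  pdet <- -expm1(-en)
  tibble::tibble(
    m = m, a = a, min_len = min_len,
    expected_n = en,
    expected_total_cm = 100 * elen,
    p_detected = pdet,
    expected_n_detected = en / pdet,
    expected_total_cm_detected = 100 * elen / pdet
  )
}

#' Probability that a sampled individual has a p-th cousin in the sample
#'
#' Simulates monogamous Wright-Fisher pedigrees: every generation the `N`
#' diploid individuals form `N/2` random couples and each child draws a
#' uniform parent couple. An individual has a p-th cousin in the sample if
#' another sampled individual shares at least one ancestor couple exactly
#' `p + 1` generations back and none more recently. In this model, with
#' `K/N = 0.2`, roughly 55% of samples have a first cousin and 95% a second
#' cousin in the cohort.
#'
#' @param K sample size (diploid individuals), `1 <= K <= N`.
#' @param N diploid population size per generation (rounded up to even).
#' @param p cousin degree (1 = first cousins).
#' @param replicates number of independent pedigree replicates.
#' @param method `"pedigree"` simulates; `"closed_form"` evaluates the cited
#'   Poisson approximation `1 - exp(-4^p (K-1) / N)` directly.
#' @param model family-size model for the simulation. `"fixed"` gives every
#'   couple exactly two children, the perfect-binary-ancestry assumption
#'   under which the cited calculation's expected `4^p` cousins (and hence
#'   the 55% / 95% figures) hold. `"wf"` draws Wright-Fisher (multinomial)
#'   family sizes; size-biased parental sibships then double the expected
#'   cousin count (to `2 * 4^p`) and containment rises to roughly 74% / 98%
#'   at `K/N = 0.2`.
#' @return A tibble with one row per degree in `p`: the mean containment
#'   probability, its across-replicate standard error, the replicate count
#'   and the method.
#' @export
cousin_containment <- function(K, N, p, replicates = 20,
                               method = c("pedigree", "closed_form"),
                               model = c("fixed", "wf")) {
  method <- match.arg(method)
  model <- match.arg(model)
  if (K > N) stop("`K` cannot exceed `N`", call. = FALSE)
  stopifnot(K >= 1, all(p >= 1), replicates >= 1)
  if (method == "closed_form") {
    return(tibble::tibble(
      p = p, K = K, N = N,
      probability = -expm1(-4^p * (K - 1) / N),
      se = NA_real_, replicates = 0L,
      method = "closed-form"
    ))
  }
  N <- as.integer(2 * ceiling(N / 2))
  ncpl <- N %/% 2L
  G <- max(p) + 1L
  draw_pc <- function() {
    if (model == "fixed") sample(rep.int(seq_len(ncpl), 2L)) else
      sample.int(ncpl, N, replace = TRUE)
  }
  per_rep <- function() {
    # parent couple of every individual at each ancestor level
    pc <- replicate(G, draw_pc(), simplify = FALSE)
    samp <- sample.int(N, K)
    # couple-ancestor sets per sample, level by level
    anc <- vector("list", G)
    cur <- tibble::tibble(sample = seq_len(K), ind = samp)
    for (lev in seq_len(G)) {
      cpl <- tibble::tibble(sample = cur$sample, couple = pc[[lev]][cur$ind])
      anc[[lev]] <- dplyr::distinct(cpl)
      cur <- anc[[lev]] |>
        dplyr::reframe(ind = c(2L * .data$couple - 1L, 2L * .data$couple),
                       .by = "sample")
    }
    # samples sharing >= 1 couple at each level
    shares <- lapply(anc, function(tab) {
      pr <- dplyr::inner_join(tab, tab, by = "couple",
                              relationship = "many-to-many") |>
        dplyr::filter(.data$sample.x != .data$sample.y) |>
        dplyr::distinct(.data$sample.x, .data$sample.y)
      pr
    })
    vapply(p, function(deg) {
      at <- shares[[deg + 1L]]
      if (deg >= 1) {
        closer <- dplyr::bind_rows(shares[seq_len(deg)]) |> dplyr::distinct()
        at <- dplyr::anti_join(at, closer, by = c("sample.x", "sample.y"))
      }
      length(unique(at$sample.x)) / K
    }, 0)
  }
  reps <- vapply(seq_len(replicates), function(i) per_rep(), numeric(length(p)))
  reps <- matrix(reps, nrow = length(p))
  tibble::tibble(
    p = p, K = K, N = N,
    probability = rowMeans(reps),
    se = apply(reps, 1, stats::sd) / sqrt(replicates),
    replicates = replicates,
    method = paste0("pedigree-simulation-", model)
  )
}

#' Expected variance of admixture ancestry proportions
#'
#' For a single migration pulse of fraction `f` that occurred `g`
#' generations ago, the across-sample variance of haploid ancestry
#' proportions is obtained from a two-locus backward co-ancestry argument.
#' Two lineages (two loci of one sample, or loci of two different samples)
#' either sit on the same haploid lineage or on different ones; per
#' generation they separate by recombination with probability
#' `c(d) = (1 - exp(-2d))/2` at map distance `d` (1/2 across chromosomes)
#' and rejoin with probability `1/(2N)`. Ancestry covariance at the pulse is
#' `f(1-f)` times the probability of co-segregating, and the expected sample
#' variance reduces to
#' `f(1-f)/L^2 * integral over (x, y) of (1 - c(d(x,y)) - 1/(2N))^g`.
#' For unlinked loci and large `N` this is the classical genealogical term
#' `f(1-f)/2^g`; the within-chromosome part is the recombination variance,
#' which decays only like `1/g` and dominates after roughly 10 generations.
#'
#' @param f pulse admixture fraction in `[0, 1]`.
#' @param g generations since the pulse (vectorised, `g >= 1`).
#' @param map a [genetic_map()].
#' @param N diploid population size (finite `N` accounts for lineages
#'   re-joining through shared ancestors; `Inf` gives the infinite-pedigree
#'   limit).
#' @return A tibble with columns `g`, `variance`, and the `genealogical` /
#'   `recombination` decomposition.
#' @examples
#' expected_ancestry_variance(0.3, g = 1:5, map = human22_map(), N = 80)
#' @export
expected_ancestry_variance <- function(f, g, map, N = Inf) {
  stopifnot(f >= 0, f <= 1, all(g >= 1), inherits(map, "genetic_map"))
  L <- map$L
  rejoin <- if (is.finite(N)) 1 / (2 * N) else 0
  lam <- function(d) 1 - (1 - exp(-2 * d)) / 2 - rejoin
  one_g <- function(gg) {
    within <- sum(vapply(map$lengths, function(l) {
      stats::integrate(function(u) 2 * (l - u) * lam(u)^gg, 0, l,
                       rel.tol = 1e-9)$value
    }, 0))
    cross <- (L^2 - sum(map$lengths^2)) * lam(Inf)^gg
    geneal <- f * (1 - f) * lam(Inf)^gg
    total <- f * (1 - f) * (within + cross) / L^2
    c(total = total, genealogical = geneal)
  }
  res <- vapply(g, one_g, c(total = 0, genealogical = 0))
  tibble::tibble(
    g = g,
    variance = unname(res["total", ]),
    genealogical = unname(res["genealogical", ]),
    recombination = unname(res["total", ] - res["genealogical", ])
  )
}
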