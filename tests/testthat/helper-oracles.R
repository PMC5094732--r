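# Independent, loop-based oracles used to cross-check the vectorized engine.

# All distinct label arrangements of a two-group outcome, observed first.
enumerateTwoGroupLabels <- function(grp) {
  lev <- levels(factor(grp))
  n <- length(grp)
  pos2 <- sort(which(grp == lev[2L]))
  subsets <- utils::combn(n, length(pos2))
  assigns <- list(grp)
  for (j in seq_len(ncol(subsets))) {
    s <- subsets[, j]
    if (identical(s, pos2)) next
    g <- rep(lev[1L], n)
    g[s] <- lev[2L]
    assigns[[length(assigns) + 1L]] <- g
  }
  assigns
}

# Brute-force NPC over the exhaustively enumerated permutation group:
# per-gene pooled two-sample |t| statistics via t.test, Eq-style pooled
# p-values with explicit counting loops, and the three combining functions.
bruteForceNPC <- function(mats, grp,
                          combiners = c("fisher", "liptak", "tippett")) {
  lev <- levels(factor(grp))
  assigns <- enumerateTwoGroupLabels(grp)
  Bp1 <- length(assigns)
  G <- nrow(mats[[1L]])
  stats <- lapply(mats, function(M) {
    S <- matrix(NA_real_, Bp1, G)
    for (b in seq_len(Bp1)) {
      for (g in seq_len(G)) {
        x <- M[g, assigns[[b]] == lev[2L]]
        y <- M[g, assigns[[b]] == lev[1L]]
        S[b, g] <- abs(stats::t.test(x, y, var.equal = TRUE)$statistic)
      }
    }
    S
  })
  lam <- lapply(stats, function(S) {
    P <- matrix(NA_real_, Bp1, G)
    for (b in seq_len(Bp1)) {
      for (g in seq_len(G)) P[b, g] <- sum(S[, g] >= S[b, g]) / Bp1
    }
    P
  })
  lo <- 1 / (2 * Bp1)
  out <- list(partial = lapply(lam, function(P) P[1L, ]))
  for (cmb in combiners) {
    Tg <- matrix(NA_real_, Bp1, G)
    for (b in seq_len(Bp1)) {
      for (g in seq_len(G)) {
        l <- vapply(lam, function(P) P[b, g], numeric(1L))
        Tg[b, g] <- switch(cmb,
          fisher = -2 * sum(log(l)),
          liptak = sum(stats::qnorm(1 - pmin(pmax(l, lo), 1 - lo))),
          tippett = max(1 - l))
      }
    }
    p <- numeric(G)
    for (g in seq_len(G)) p[g] <- sum(Tg[, g] >= Tg[1L, g]) / Bp1
    out[[cmb]] <- p
  }
  out
}

# Classical Cochran-Armitage closed form for a 2x3 table (scores 0,1,2):
# cases/controls are counts per genotype.
caTrendChisq <- function(cases, controls, scores = 0:2) {
  nk <- cases + controls
  N <- sum(nk); R <- sum(cases)
  pbar <- R / N
  Tstat <- sum(scores * cases) - pbar * sum(scores * nk)
  V <- pbar * (1 - pbar) * (sum(scores^2 * nk) - sum(scores * nk)^2 / N)
  Tstat^2 / V
}

# small deterministic two-group study for engine tests
makeToyStudy <- function(nGenes = 30L, perGroup = 3L, nModalities = 2L,
                         seed = 1L, shift = 1.5, deFrac = 0.3) {
  set.seed(seed)
  n <- 2L * perGroup
  sid <- sprintf("s%02d", seq_len(n))
  gid <- sprintf("g%03d", seq_len(nGenes))
  de <- seq_len(ceiling(deFrac * nGenes))
  mats <- lapply(seq_len(nModalities), function(i) {
    m <- matrix(stats::rnorm(nGenes * n), nGenes, n,
                dimnames = list(gid, sid))
    m[de, (perGroup + 1L):n] <- m[de, (perGroup + 1L):n] + shift
    m
  })
  datasets <- lapply(seq_along(mats), function(i)
    OmicsDataset(mats[[i]], "continuous", paste0("mod", i)))
  design <- StudyDesign(sid, rep(c("a", "b"), each = perGroup))
  list(mats = mats, datasets = datasets, design = design, de = de)
}
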