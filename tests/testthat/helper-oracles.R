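# Independent brute-force oracles used across test files. These deliberately
# re-derive results by naive enumeration, never by calling the package's own
# vectorized implementations.

# per-site, per-sample loop evaluation of the screening filters
oracle_screen <- function(panel, filters) {
  sites <- panel$sites
  samp <- panel$samples
  hap <- panel$haplotypes
  pass <- logical(nrow(sites))
  for (j in seq_len(nrow(sites))) {
    ok <- TRUE
    if (filters$african_fixed_ancestral) {
      for (i in which(samp$group == "AFRICAN")) {
        for (h in 1:2) {
          v <- hap[2 * (i - 1) + h, j]
          if (!is.na(v) && v == 1) ok <- FALSE
        }
      }
    }
    if (filters$neandertal_hom_derived) {
      n_obs <- 0
      for (i in which(samp$group == "NEANDERTAL")) {
        v1 <- hap[2 * (i - 1) + 1, j]
        v2 <- hap[2 * (i - 1) + 2, j]
        if (!is.na(v1) && !is.na(v2)) {
          n_obs <- n_obs + 1
          if (!(v1 == 1 && v2 == 1)) ok <- FALSE
        }
      }
      if (n_obs < filters$min_neandertal_obs) ok <- FALSE
    }
    if (filters$denisovan_absent) {
      for (i in which(samp$group == "DENISOVAN")) {
        for (h in 1:2) {
          v <- hap[2 * (i - 1) + h, j]
          if (!is.na(v) && v == 1) ok <- FALSE
        }
      }
    }
    if (!is.null(filters$consequences) &&
        !(sites$consequence[j] %in% filters$consequences)) ok <- FALSE
    if (!is.null(filters$genes) && length(filters$genes) &&
        (is.na(sites$gene[j]) || !(sites$gene[j] %in% filters$genes))) ok <- FALSE
    pass[j] <- ok
  }
  sites$id[pass]
}

# highest-averages schedule by explicit quotient enumeration
oracle_sainte_lague <- function(total, weights) {
  alloc <- integer(length(weights))
  if (total == 0) return(alloc)
  q <- expand.grid(bin = seq_along(weights), k = seq_len(total))
  q$quotient <- weights[q$bin] / (2 * q$k - 1)
  q <- q[order(-q$quotient, -weights[q$bin], q$bin), ]
  won <- q$bin[seq_len(total)]
  for (b in won) alloc[b] <- alloc[b] + 1L
  alloc
}

# naive double-loop Hamming distances
oracle_hamming <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

# small default panel scenario used where the full African sample size is
# not the point of the test
small_panel_scenario <- function(...) {
  defaults <- list(n_african = 25, n_modern = c(A = 10, B = 10),
                   n_background = 20, n_tract_sites = 15, n_decoys = 8,
                   introgressed_fraction = 0.15)
  do.call(panel_scenario, utils::modifyList(defaults, list(...)))
}
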