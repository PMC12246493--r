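test_that("prepare_alignment applies the archaic site rules", {
  sim <- sim_genotype_panel(small_panel_scenario(), seed = 51)
  region <- sim$scenario$region
  aln <- prepare_alignment(sim$panel, region, "rs34526199")
  # characters stay binary
  expect_true(all(aln$matrix %in% c(0L, 1L)))
  # root taxon present and all-ancestral
  expect_true("ancestral" %in% rownames(aln$matrix))
  expect_true(all(aln$matrix["ancestral", ] == 0))
  # all carriers included, one representative per non-carrier population
  expect_true(all(sim$carriers %in% rownames(aln$matrix)))
  reps <- aln$taxa$taxon[aln$taxa$role == "representative"]
  expect_length(reps, 2)
  # sites heterozygous in any archaic are gone
  arch_g <- panel_genotypes(sim$panel, c("NEANDERTAL", "DENISOVAN"))
  het_pos <- sim$panel$sites$pos[colSums(arch_g == 1, na.rm = TRUE) > 0]
  expect_true(all(het_pos %in% aln$excluded_sites))
  expect_false(any(het_pos %in% aln$positions))
})

test_that("missing archaic calls are imputed to the ancestral allele and flagged", {
  sim <- sim_genotype_panel(small_panel_scenario(archaic_missing_rate = 0.2),
                            seed = 52)
  aln <- prepare_alignment(sim$panel, sim$scenario$region, "rs34526199")
  # per-site audit on a manual subset: every imputed cell is 0 and was NA
  g <- panel_genotypes(sim$panel, c("NEANDERTAL", "DENISOVAN"))
  arch <- rownames(g)
  col_of <- match(aln$positions, sim$panel$sites$pos)
  n_missing_retained <- 0
  for (tx in arch) {
    for (j in seq_along(aln$positions)) {
      if (is.na(g[tx, col_of[j]])) {
        n_missing_retained <- n_missing_retained + 1
        expect_equal(unname(aln$matrix[tx, j]), 0L)
        expect_true(aln$imputed[tx, j])
      } else {
        expect_false(aln$imputed[tx, j])
      }
    }
  }
  expect_equal(sum(aln$imputed), n_missing_retained)
  expect_gt(n_missing_retained, 0)
})

test_that("hamming_distances equals the naive double loop", {
  expect_equal(hamming_distances(rbind(a = c(0, 1, 0, 1),
                                       b = c(0, 0, 1, 1),
                                       c = c(0, 1, 0, 1)))["a", "b"], 2)
  set.seed(61)
  m <- matrix(rbinom(20 * 50, 1, 0.4), 20, 50,
              dimnames = list(paste0("t", 1:20), NULL))
  expect_equal(hamming_distances(m), oracle_hamming(m))
  d <- hamming_distances(m)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("nj_tree solves 3 and 4 taxon cases in closed form", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(d3)
  co <- ape::cophenetic.phylo(tr3)[rownames(d3), colnames(d3)]
  expect_equal(co, d3, tolerance = 1e-9)
  # the spec four-point example: tree ((A:1,B:2):1,(C:3,D:4))
  lab <- c("A", "B", "C", "D")
  d4 <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
               dimnames = list(lab, lab))
  tr4 <- nj_tree(d4)
  expect_equal(ape::cophenetic.phylo(tr4)[lab, lab], d4, tolerance = 1e-9)
  # split AB|CD present
  rooted <- ape::root(tr4, outgroup = "D", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, c("A", "B")))
  expect_error(nj_tree(matrix(c(0, 1, 1, 0), 2, 2)), "3 taxa")
  expect_error(nj_tree(matrix(c(0, 1, 5, 2, 0, 1, 1, 1, 0), 3, 3)),
               "symmetric")
})

test_that("nj_tree recovers additive trees exactly and matches ape::nj", {
  set.seed(71)
  for (n in 4:10) {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 3))
    tr <- ape::unroot(tr)
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d)
    # exact recovery: tree distances reproduce the additive matrix
    expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
    expect_equal(ape::dist.topo(rec, tr), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    # independent implementation agrees on generic (noisy) matrices too
    dn <- d + matrix(runif(n^2, 0, 0.05), n, n)
    dn <- (dn + t(dn)) / 2
    diag(dn) <- 0
    expect_equal(as.numeric(ape::dist.topo(nj_tree(dn), ape::nj(dn))), 0)
  }
})

test_that("nj_tree is invariant to taxon order", {
  set.seed(72)
  tr <- ape::unroot(ape::rtree(8))
  d <- ape::cophenetic.phylo(tr)
  perm <- sample(8)
  t1 <- nj_tree(d)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("clade_support is deterministic, bounded and saturates on clean signal", {
  # 30 conflict-free supporting sites: support 1.0
  m <- rbind(
    in1 = c(rep(1, 30), rep(0, 5)),
    in2 = c(rep(1, 30), rep(0, 5)),
    out1 = c(rep(0, 30), rep(1, 5)),
    out2 = rep(0, 35),
    out3 = c(rep(0, 30), rep(1, 3), 0, 0)
  )
  aln <- structure(list(matrix = m, positions = seq_len(ncol(m)),
                        taxa = tibble::tibble(taxon = rownames(m),
                                              role = "carrier"),
                        imputed = m * 0 > 0, excluded_sites = numeric(0)),
                   class = "haplotype_alignment")
  cs <- clade_support(aln, B = 100, seed = 2)
  expect_equal(support_for_clade(cs, c("in1", "in2")), 1.0)
  # deterministic given seed
  cs2 <- clade_support(aln, B = 100, seed = 2)
  expect_identical(cs$support, cs2$support)
  # B = 1: supports in {0, 1}
  cs1 <- clade_support(aln, B = 1, seed = 9)
  expect_true(all(cs1$support$support %in% c(0, 1)))
  expect_true(all(cs$support$support >= 0 & cs$support$support <= 1))
})

test_that("monophyly checks behave on trivial subsets and unknown taxa", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:2);")
  expect_true(is_monophyletic_clade(tr, c("A", "B"), "E"))
  expect_true(is_monophyletic_clade(tr, "A", "E"))
  # all leaves except the root taxon form a clade after rooting
  expect_true(is_monophyletic_clade(tr, c("A", "B", "C", "D"), "E"))
  expect_false(is_monophyletic_clade(tr, c("A", "C"), "E"))
  expect_error(is_monophyletic_clade(tr, "Z", "E"), "unknown taxon")
})

test_that("alignment converts to DNAbin for FASTA export", {
  m <- rbind(x = c(0, 1, 1), y = c(1, 0, 1), z = c(0, 0, 0))
  aln <- structure(list(matrix = m, positions = 1:3,
                        taxa = tibble::tibble(taxon = rownames(m),
                                              role = "carrier"),
                        imputed = m > 2, excluded_sites = numeric(0)),
                   class = "haplotype_alignment")
  db <- alignment_to_DNAbin(aln)
  expect_s3_class(db, "DNAbin")
  ch <- as.character(db)
  expect_equal(unname(ch["x", ]), c("a", "t", "t"))
})
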