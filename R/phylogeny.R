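#' Build the haplotype alignment over a genomic region
#'
#' Assembles the character matrix for the haplotype phylogeny: all modern
#' haplotypes carrying the derived focal allele, one representative
#' haplotype per modern population without it (the first in sample order),
#' one taxon per archaic genome, and an all-ancestral root taxon. Archaic
#' genotypes are collapsed per site: homozygous calls give the allele,
#' sites heterozygous in any archaic are excluded, and missing archaic
#' calls are imputed to the ancestral-coded reference allele and flagged.
#' Only bi-allelic sites inside the region are retained.
#'
#' @param panel A [genotype_panel].
#' @param region A [genomic_interval]; typically the core haplotype.
#' @param focal_id Id of the focal variant (must lie inside the region).
#' @param per_population Representative non-carrier haplotypes per modern
#'   population (default 1; 0 drops non-carriers).
#' @param root_label Name of the inferred-ancestral root taxon.
#' @return An object of class `haplotype_alignment`: `matrix` (taxa x
#'   sites, 0/1), `positions`, `taxa` (tibble: `taxon`, `role`), `imputed`
#'   (logical matrix marking imputed archaic cells), `excluded_sites`
#'   (positions dropped for archaic heterozygosity).
#' @export
prepare_alignment <- function(panel, region, focal_id, per_population = 1,
                              root_label = "ancestral") {
  stopifnot(inherits(panel, "genotype_panel"))
  sites <- panel$sites
  in_region <- sites$pos >= region$start & sites$pos <= region$end &
    nchar(sites$ref) == 1 & nchar(sites$alt) == 1
  if (sum(in_region) < 2) stop("region contains fewer than 2 bi-allelic sites",
                               call. = FALSE)
  k_focal <- which(sites$id == focal_id)
  if (!length(k_focal)) stop("focal variant not in panel", call. = FALSE)

  hap <- panel$haplotypes[, in_region, drop = FALSE]
  pos <- sites$pos[in_region]
  focal_col <- match(sites$pos[k_focal], pos)
  if (is.na(focal_col)) stop("focal variant outside region", call. = FALSE)

  samp <- panel$samples
  hap_group <- rep(samp$group, each = 2)
  hap_pop <- rep(samp$population, each = 2)
  hap_names <- rownames(panel$haplotypes)

  mod <- which(hap_group == "MODERN")
  carrier <- mod[!is.na(hap[mod, focal_col]) & hap[mod, focal_col] == 1]
  rows <- carrier
  if (per_population > 0) {
    for (p in unique(hap_pop[mod])) {
      non <- mod[hap_pop[mod] == p &
                   (is.na(hap[mod, focal_col]) | hap[mod, focal_col] == 0)]
      rows <- c(rows, utils::head(non, per_population))
    }
  }
  modern_mat <- hap[rows, , drop = FALSE]
  modern_mat[is.na(modern_mat)] <- 0L
  modern_roles <- ifelse(rows %in% carrier, "carrier", "representative")

  arch_idx <- which(samp$group %in% c("NEANDERTAL", "DENISOVAN"))
  arch_mat <- NULL
  arch_imp <- NULL
  het_any <- rep(FALSE, ncol(hap))
  if (length(arch_idx)) {
    g <- panel_genotypes(panel)[arch_idx, in_region, drop = FALSE]
    het_any <- colSums(g == 1, na.rm = TRUE) > 0
    arch_imp <- is.na(g)
    arch_mat <- matrix(0L, nrow(g), ncol(g), dimnames = dimnames(g))
    arch_mat[g == 2] <- 1L
    arch_mat[is.na(g)] <- 0L # imputed to the ancestral-coded reference
  }

  keep <- !het_any
  out_mat <- rbind(
    arch_mat[, keep, drop = FALSE],
    modern_mat[, keep, drop = FALSE],
    matrix(0L, 1, sum(keep), dimnames = list(root_label, NULL))
  )
  if (ncol(out_mat) == 0) stop("empty alignment after archaic-site exclusion",
                               call. = FALSE)
  taxa <- tibble::tibble(
    taxon = c(samp$sample_id[arch_idx], hap_names[rows], root_label),
    role = c(tolower(samp$group[arch_idx]), modern_roles, "root")
  )
  rownames(out_mat) <- taxa$taxon
  imputed <- rbind(
    if (!is.null(arch_imp)) arch_imp[, keep, drop = FALSE],
    matrix(FALSE, nrow(modern_mat) + 1, sum(keep))
  )
  rownames(imputed) <- taxa$taxon
  structure(list(matrix = out_mat, positions = pos[keep], taxa = taxa,
                 imputed = imputed, excluded_sites = pos[!keep],
                 focal_id = focal_id),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("<haplotype_alignment> %d taxa x %d sites (%d excluded, %d imputed cells)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$excluded_sites),
              sum(x$imputed)))
  invisible(x)
}

#' Pairwise Hamming distance matrix
#'
#' Number of differing sites between each pair of taxa.
#'
#' @param x A `haplotype_alignment` or a 0/1 character matrix (taxa in
#'   rows).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
hamming_distances <- function(x) {
  m <- if (inherits(x, "haplotype_alignment")) x$matrix else x
  stopifnot(is.matrix(m), nrow(m) >= 3)
  as.matrix(stats::dist(m, method = "manhattan"))
}

#' Neighbor-joining tree (canonical Saitou-Nei agglomeration)
#'
#' Standard NJ on a distance matrix: at each step the pair minimizing the
#' Q criterion `Q_ij = (n-2) d_ij - r_i - r_j` is joined; ties are broken
#' by the lowest (row, column) index pair for determinism. Negative branch
#' lengths are clamped to zero with the deficit moved to the sibling
#' branch. Additive distance matrices are recovered exactly.
#'
#' @param d Symmetric distance matrix with at least 3 labelled taxa.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n0 <- nrow(d)
  if (n0 < 3) stop("need at least 3 taxa", call. = FALSE)
  labels <- rownames(d) %||% paste0("t", seq_len(n0))
  # each active node carries its newick subtree string
  nwk <- labels
  active <- seq_len(n0)
  D <- d
  fmt <- function(x) sprintf("%.12g", max(0, x))
  while (length(active) > 3) {
    n <- length(active)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest (row, col) pair among minima, scanning i < j
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- D[i, j]; li <- 0 }
    if (lj < 0) { li <- D[i, j]; lj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    active <- seq_len(n - 1)
  }
  # final three nodes: closed-form three-point branch lengths
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(la), nwk[2], fmt(lb),
                 nwk[3], fmt(lc))
  ape::read.tree(text = txt)
}

#' Site-bootstrap clade support for the NJ haplotype tree
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `B` times, rebuilds the tree from each
#' pseudo-alignment, and reports for each internal edge of the original
#' tree the fraction of replicate trees containing the same bipartition.
#'
#' @param alignment A `haplotype_alignment` with at least 4 taxa.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the site resampling.
#' @return A list of class `clade_support`: `tree` (the NJ `phylo` with
#'   node labels set to supports), `support` (tibble: `node`, `support`),
#'   `B`.
#' @export
clade_support <- function(alignment, B = 100, seed = 1) {
  stopifnot(inherits(alignment, "haplotype_alignment"), B >= 1)
  m <- alignment$matrix
  if (nrow(m) < 4) stop("need at least 4 taxa for internal edges", call. = FALSE)
  tree <- nj_tree(hamming_distances(m))
  boots <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      nj_tree(hamming_distances(m[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / B
  tree$node.label <- support
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  structure(list(
    tree = tree,
    support = tibble::tibble(node = nrow(m) + seq_along(support),
                             support = support,
                             tips = lapply(pp, function(ix) labs[ix])),
    B = B
  ), class = "clade_support")
}

#' Bootstrap support of a specific taxon set
#'
#' Looks up the support of the bipartition separating `taxa` from the rest
#' of the tree in a [clade_support()] result. Returns `NA` when the taxon
#' set does not form an edge of the tree.
#'
#' @param cs A `clade_support` object.
#' @param taxa Character vector of tip labels.
#' @return Support in \[0, 1\], or `NA_real_`.
#' @export
support_for_clade <- function(cs, taxa) {
  stopifnot(inherits(cs, "clade_support"))
  all_tips <- cs$tree$tip.label
  for (i in seq_len(nrow(cs$support))) {
    tips <- cs$support$tips[[i]]
    if (setequal(tips, taxa) || setequal(setdiff(all_tips, tips), taxa)) {
      return(cs$support$support[i])
    }
  }
  NA_real_
}

#' @export
print.clade_support <- function(x, ...) {
  cat(sprintf("<clade_support> %d-taxon NJ tree, B = %d site-bootstrap replicates\n",
              length(x$tree$tip.label), x$B))
  print(summary(x$support$support))
  invisible(x)
}

#' @export
tidy.clade_support <- function(x, ...) x$support

#' Monophyly check after rooting
#'
#' Roots the tree at the given root taxon and tests whether the named taxa
#' are exactly the leaf set of some clade.
#'
#' @param tree A `phylo` tree.
#' @param taxa Character vector of tip labels.
#' @param root_taxon Tip to root at (e.g. the inferred ancestral sequence).
#' @return Logical flag.
#' @export
is_monophyletic_clade <- function(tree, taxa, root_taxon) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(c(taxa, root_taxon), tree$tip.label)
  if (length(unknown)) stop("unknown taxon: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  rooted <- ape::root(tree, outgroup = root_taxon, resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}

#' Convert a haplotype alignment to a DNAbin object
#'
#' Encodes 0 (ancestral) as `a` and 1 (derived) as `t`, which lets the
#' alignment be written as FASTA with [ape::write.FASTA()] and inspected
#' with standard sequence tools.
#'
#' @param alignment A `haplotype_alignment`.
#' @return An `ape` `DNAbin` matrix.
#' @export
alignment_to_DNAbin <- function(alignment) {
  stopifnot(inherits(alignment, "haplotype_alignment"))
  chars <- ifelse(alignment$matrix == 1L, "t", "a")
  ape::as.DNAbin(matrix(chars, nrow = nrow(alignment$matrix),
                        dimnames = dimnames(alignment$matrix)))
}
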