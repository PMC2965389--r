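# Leader-sequence clustering into attenuator regulons.
#
# Candidate leaders are compared all-against-all by local alignment
# (Smith-Waterman-Gotoh, affine gaps); raw scores are converted to bits with
# the Karlin-Altschul formula, the pairwise distance is the inverse bit
# score (capped for non-matching pairs), and complete-linkage hierarchical
# clustering is cut at 0.038 -- i.e. pairs must share a local alignment of
# at least ~26.3 bits (E ~ 1e-4 for leader-sized sequences) to co-cluster.

#' Alignment scoring scheme with Karlin-Altschul parameters
#'
#' The ungapped lambda is solved numerically from
#' sum_ij p_i p_j exp(lambda * s_ij) = 1 on the background base composition;
#' K defaults to the published ungapped value for match +1 / mismatch -2 on
#' uniform background.
#'
#' @param match,mismatch Match/mismatch scores (match > 0 > mismatch).
#' @param gap_open,gap_extend Affine gap penalties (positive costs; a gap of
#'   length k costs gap_open + k * gap_extend).
#' @param K Karlin-Altschul K.
#' @param background Base frequencies for A, C, G, T.
#' @return A list of class `align_scoring` including the solved `lambda`.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap_open = 2,
                          gap_extend = 1, K = 0.621,
                          background = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25)) {
  stopifnot(match > 0, mismatch < 0, gap_open > 0, gap_extend > 0, K > 0)
  p <- background / sum(background)
  pmatch <- sum(p^2)
  f <- function(lam) pmatch * exp(lam * match) +
    (1 - pmatch) * exp(lam * mismatch) - 1
  lambda <- uniroot(f, c(1e-8, 10), tol = 1e-12)$root
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, K = K, lambda = lambda,
                 background = p),
            class = "align_scoring")
}

#' Local alignment score between two sequences, in bits
#'
#' Best local alignment raw score under affine gaps, converted to bits as
#' (lambda * raw - ln K) / ln 2.  Returns 0 when the best raw score is <= 0.
#' Symmetric in its two arguments.
#'
#' @param a,b DNA sequences (character strings).
#' @param sc An [align_scoring()] scheme.
#' @return Bit score (numeric scalar).
#' @export
local_alignment_score <- function(a, b, sc = align_scoring()) {
  stopifnot(nzchar(a), nzchar(b))
  raw <- raw_local_score(a, b, sc)
  if (raw <= 0) return(0)
  (sc$lambda * raw - log(sc$K)) / log(2)
}

#' @noRd
raw_local_score <- function(a, b, sc) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = sc$match, mismatch = sc$mismatch, baseOnly = TRUE)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(normalize_sequence(a)),
    Biostrings::DNAString(normalize_sequence(b)),
    type = "local", substitutionMatrix = mat,
    gapOpening = sc$gap_open, gapExtension = sc$gap_extend,
    scoreOnly = TRUE))
}

# Hard-mask homopolymer runs (>= min_run identical bases) to N, the
# low-complexity filter terminator tails require: without it every leader
# pair shares its poly-T run and unrelated leaders collect ~26 bits.
#' @noRd
mask_homopolymers <- function(x, min_run = 5L) {
  pat <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}",
                 min_run, min_run, min_run, min_run)
  vapply(x, function(s) {
    m <- gregexpr(pat, s)[[1]]
    if (m[1] == -1) return(s)
    len <- attr(m, "match.length")
    for (k in seq_along(m))
      substr(s, m[k], m[k] + len[k] - 1L) <- strrep("N", len[k])
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Pairwise inverse-bit-score distance matrix over leaders
#'
#' d(i, j) = 1 / bits(i, j) when bits > 1 / cap, otherwise `cap` (the
#' distance assigned to non-matching pairs).  Before alignment,
#' homopolymer runs of `mask_min_run` or more bases are hard-masked
#' (N scores as a mismatch against bases and 0 against N): every leader
#' ends in a poly-T terminator tail, and without low-complexity masking
#' those shared runs alone pull unrelated pairs under the cluster cut.
#'
#' @param leaders Named character vector of leader sequences (>= 2).
#' @param sc An [align_scoring()] scheme.
#' @param cap Distance for non-matching pairs.
#' @param mask_min_run Minimal homopolymer run length to mask; `Inf`
#'   disables masking.
#' @return A symmetric matrix with zero diagonal and `cap` attribute.
#' @export
pairwise_distance_matrix <- function(leaders, sc = align_scoring(),
                                     cap = 1.0, mask_min_run = 5L) {
  n <- length(leaders)
  stopifnot(n >= 2)
  if (is.null(names(leaders))) names(leaders) <- paste0("leader", seq_len(n))
  lets <- c("A", "C", "G", "T", "N")
  mat <- matrix(sc$mismatch, 5, 5, dimnames = list(lets, lets))
  diag(mat) <- sc$match
  mat["N", ] <- mat[, "N"] <- sc$mismatch
  mat["N", "N"] <- 0
  seqs <- normalize_sequence(leaders)
  if (is.finite(mask_min_run)) seqs <- mask_homopolymers(seqs, mask_min_run)
  names(seqs) <- names(leaders)
  set <- Biostrings::DNAStringSet(seqs)
  d <- matrix(0, n, n, dimnames = list(names(leaders), names(leaders)))
  for (i in seq_len(n - 1)) {
    raw <- as.numeric(Biostrings::pairwiseAlignment(
      set[(i + 1):n], set[[i]], type = "local", substitutionMatrix = mat,
      gapOpening = sc$gap_open, gapExtension = sc$gap_extend,
      scoreOnly = TRUE))
    bits <- ifelse(raw <= 0, 0, (sc$lambda * raw - log(sc$K)) / log(2))
    dij <- ifelse(bits > 1 / cap, 1 / bits, cap)
    d[i, (i + 1):n] <- dij
    d[(i + 1):n, i] <- dij
  }
  attr(d, "cap") <- cap
  d
}

#' Hierarchical clustering of leaders with a fixed cut height
#'
#' Agglomerative clustering (default complete linkage) of the distance
#' matrix; flat clusters contain all merges of height <= `h`, so a pair at
#' exactly the cut height is merged.
#'
#' @param dm A [pairwise_distance_matrix()] matrix (or `dist`).
#' @param linkage `hclust` agglomeration method.
#' @param h Cut height (default 0.038, i.e. ~26.3 bits).
#' @return A list of class `cluster_set`: `membership` (named integer
#'   vector), `clusters` (list of member-id vectors), `tree` (`hclust`),
#'   `cut_height`.
#' @export
cluster_and_cut <- function(dm, linkage = "complete", h = 0.038) {
  d <- if (inherits(dm, "dist")) dm else as.dist(dm)
  tree <- hclust(d, method = linkage)
  memb <- cutree(tree, h = h)
  clusters <- split(names(memb), memb)
  names(clusters) <- paste0("cluster", names(clusters))
  structure(list(membership = memb, clusters = clusters, tree = tree,
                 cut_height = h),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("cluster_set: %d leaders in %d clusters at h = %g (%d multi-member)\n",
              length(x$membership), length(x$clusters), x$cut_height,
              sum(sizes > 1)))
  invisible(x)
}

#' Classify a cluster by the families of its downstream genes
#'
#' Class `"a"`: all members' downstream genes belong to one family
#' (orthologous regulation); `"c"`: a super-cluster with at least two
#' families each represented at least twice; `"b"`: anything else
#' (non-orthologous genes, possibly one species).
#'
#' @param families Character vector: the family of each member's downstream
#'   gene (`NA` treated as `"unassigned"`).
#' @return `"a"`, `"b"` or `"c"`.
#' @export
classify_cluster <- function(families) {
  families[is.na(families)] <- "unassigned"
  tab <- table(families)
  if (length(tab) == 1) "a"
  else if (sum(tab >= 2) >= 2) "c"
  else "b"
}

#' Flag mobile (insertion-sequence derived) attenuator clusters
#'
#' @param products Character vector of downstream-gene product annotations.
#' @param keywords Case-insensitive keywords marking IS/transposon genes.
#' @return `TRUE` if any product matches a keyword.
#' @export
flag_mobile <- function(products,
                        keywords = c("transposase", "insertion sequence",
                                     "integrase", "IS element", "prophage")) {
  any(vapply(keywords, function(k)
    any(grepl(k, products, ignore.case = TRUE, fixed = FALSE)),
    logical(1)))
}

#' Cluster candidate leaders into regulons
#'
#' Runs the full regulon analysis on a candidates table: pairwise distances,
#' complete-linkage clustering cut at `h`, per-cluster class (a/b/c by
#' downstream-gene families) and mobile flag (by downstream-gene products).
#'
#' @param candidates Candidates with `candidate_id`, `leader_seq`,
#'   `downstream_gene_id` (and `species_id`).
#' @param family_map Data frame with `gene_id`, `family_id`.
#' @param ann_list Named list of `genome_annotation` (per species), used to
#'   look up downstream-gene products for the mobile flag; may be `NULL`.
#' @param sc,cap,linkage,h Clustering settings (see
#'   [pairwise_distance_matrix()] and [cluster_and_cut()]).
#' @param keywords Passed to [flag_mobile()].
#' @return A list of class `regulon_clusters`: `clusters` (data frame:
#'   cluster, n_members, class, mobile), `members` (data frame: cluster,
#'   candidate_id, family), `cluster_set`, `distance_matrix`.
#' @export
cluster_leaders <- function(candidates, family_map, ann_list = NULL,
                            sc = align_scoring(), cap = 1.0,
                            linkage = "complete", h = 0.038,
                            keywords = c("transposase", "insertion sequence",
                                         "integrase", "IS element",
                                         "prophage")) {
  stopifnot(nrow(candidates) >= 2)
  leaders <- setNames(candidates$leader_seq, candidates$candidate_id)
  dm <- pairwise_distance_matrix(leaders, sc, cap)
  cs <- cluster_and_cut(dm, linkage, h)
  fam <- candidate_families(candidates, family_map)
  names(fam) <- candidates$candidate_id
  products <- rep(NA_character_, nrow(candidates))
  if (!is.null(ann_list)) {
    for (i in seq_len(nrow(candidates))) {
      sp <- candidates$species_id[i]
      g <- ann_list[[sp]]$genes
      j <- match(candidates$downstream_gene_id[i], g$gene_id)
      if (!is.na(j)) products[i] <- g$product[j]
    }
  }
  names(products) <- candidates$candidate_id
  cl_tab <- do.call(rbind, lapply(names(cs$clusters), function(cl) {
    ids <- cs$clusters[[cl]]
    data.frame(cluster = cl, n_members = length(ids),
               class = classify_cluster(fam[ids]),
               mobile = if (all(is.na(products[ids]))) NA
                        else flag_mobile(products[ids], keywords),
               stringsAsFactors = FALSE)
  }))
  members <- data.frame(
    cluster = paste0("cluster", cs$membership[candidates$candidate_id]),
    candidate_id = candidates$candidate_id,
    family = unname(fam), stringsAsFactors = FALSE)
  structure(list(clusters = cl_tab, members = members, cluster_set = cs,
                 distance_matrix = dm),
            class = "regulon_clusters")
}

#' Export a cluster dendrogram as Newick
#'
#' @param cs A `cluster_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(cs, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  ape::write.tree(ape::as.phylo(cs$tree), file = path)
  invisible(path)
}
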