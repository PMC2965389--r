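# Gene-family attenuation scores and enrichment tests.
#
# Three scores rank families by attenuation propensity: the absolute count
# of candidate attenuators across all species; a normalized score summing
# per-species candidate fractions (candidates / family genes in that
# species), which removes the large-paralog-family bias; and a
# phylogeny-weighted score that multiplies each per-species fraction lying in
# a run of L consecutive attenuated species (in the supplied phylogenetic
# order) by 1 + run_weight * L, favoring evolutionarily parsimonious
# distributions over scattered ones.  Enrichment significance is a one-sided
# hypergeometric (Fisher) test per family.

#' Read a gene-to-family map
#'
#' @param path TSV with columns `gene_id`, `species_id`, `family_id`.
#' @return The family map data frame.
#' @export
read_family_map <- function(path) {
  fm <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("gene_id", "species_id", "family_id")
  miss <- setdiff(req, names(fm))
  if (length(miss)) stop("family map lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(fm$gene_id))
    stop("gene(s) assigned to more than one family: ",
         fm$gene_id[anyDuplicated(fm$gene_id)])
  fm
}

#' @noRd
candidate_families <- function(candidates, family_map) {
  fam <- family_map$family_id[match(candidates$downstream_gene_id,
                                    family_map$gene_id)]
  fam[is.na(fam)] <- "unassigned"
  fam
}

#' Absolute family scores
#'
#' Counts candidate attenuators per family of the downstream gene, across
#' all species (one count per downstream-gene occurrence).  Genes without a
#' family are pooled under `"unassigned"`.
#'
#' @param candidates Candidates data frame (needs `downstream_gene_id`).
#' @param family_map Data frame with `gene_id`, `species_id`, `family_id`.
#' @return Named integer vector of counts (descending).
#' @export
absolute_family_scores <- function(candidates, family_map) {
  if (!nrow(candidates)) return(setNames(integer(0), character(0)))
  tab <- table(candidate_families(candidates, family_map))
  sort(setNames(as.integer(tab), names(tab)), decreasing = TRUE)
}

#' Normalized and phylogeny-weighted family scores
#'
#' For family f and species s with g_s family genes and c_s candidates,
#' b_s = c_s / g_s; the normalized score is sum(b_s).  For the weighted
#' score each b_s is multiplied by (1 + run_weight * L_s), where L_s is the
#' length of the maximal run of consecutive species with b > 0 (in
#' `species_order`) containing s; `mode = "additive"` instead adds
#' run_weight * L per run to the normalized score.
#'
#' @inheritParams absolute_family_scores
#' @param species_order Character vector: all screened species in
#'   phylogenetic order.
#' @param run_weight Weight per unit run length (default 0.1).
#' @param mode `"multiplicative"` (default) or `"additive"` run weighting.
#' @return Data frame with `family_id`, `normalized_score`, `weighted_score`.
#' @export
normalized_family_scores <- function(candidates, family_map, species_order,
                                     run_weight = 0.1,
                                     mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  sp_present <- unique(family_map$species_id)
  if (!all(sp_present %in% species_order))
    stop("species_order must cover every species in the family map")
  fam <- candidate_families(candidates, family_map)
  sp <- candidates$species_id
  if (is.null(sp)) stop("candidates need a species_id column")
  genes_per <- table(family_map$family_id, family_map$species_id)
  fams <- sort(unique(fam))
  res <- lapply(fams, function(f) {
    if (f == "unassigned")  # no family size -> not normalizable
      return(data.frame(family_id = f, normalized_score = NA_real_,
                        weighted_score = NA_real_, stringsAsFactors = FALSE))
    b <- numeric(length(species_order))
    names(b) <- species_order
    cs <- table(sp[fam == f])
    for (s in names(cs)) {
      g <- if (f %in% rownames(genes_per) && s %in% colnames(genes_per))
        genes_per[f, s] else 0L
      if (g == 0L)
        stop(sprintf("family %s has %d candidate(s) but no genes in %s",
                     f, cs[[s]], s))
      b[s] <- cs[[s]] / g
    }
    nz <- b > 0
    runs <- rle(nz)
    run_id <- rep(seq_along(runs$lengths), runs$lengths)
    run_len <- runs$lengths[run_id]
    normalized <- sum(b)
    weighted <- if (mode == "multiplicative")
      sum(b * ifelse(nz, 1 + run_weight * run_len, 1))
    else
      normalized + run_weight * sum(runs$lengths[runs$values])
    data.frame(family_id = f, normalized_score = normalized,
               weighted_score = weighted, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' One-sided Fisher enrichment probability
#'
#' Probability of observing at least `n_hit_family` attenuated genes in a
#' family of `n_genes_family` genes, when `n_hit_total` of `n_genes_total`
#' genes are attenuated (hypergeometric upper tail; equivalent to a
#' one-sided Fisher exact test on the 2x2 table).
#'
#' @param n_genes_family Genes in the family.
#' @param n_genes_total Total genes assessed.
#' @param n_hit_family Attenuated genes in the family.
#' @param n_hit_total Total attenuated genes.
#' @return Enrichment p-value(s) in (0, 1].  Vectorized.
#' @export
fisher_enrichment <- function(n_genes_family, n_genes_total, n_hit_family,
                              n_hit_total) {
  if (any(n_hit_family < 0) || any(n_hit_family > n_genes_family) ||
      any(n_hit_family > n_hit_total) || any(n_genes_family > n_genes_total) ||
      any(n_hit_total > n_genes_total))
    stop("inconsistent contingency-table margins")
  stats::phyper(n_hit_family - 1, n_genes_family,
                n_genes_total - n_genes_family, n_hit_total,
                lower.tail = FALSE)
}

#' Rank family scores
#'
#' Stable descending sort by the chosen score; ties broken by ascending
#' Fisher p, then lexicographic family id.
#'
#' @param scores A data frame with `family_id`, `absolute_score`,
#'   `weighted_score` and `fisher_p` columns (see [score_families()]).
#' @param by `"weighted"` or `"absolute"`.
#' @return The reordered data frame with a `rank` column.
#' @export
rank_families <- function(scores, by = c("weighted", "absolute")) {
  by <- match.arg(by)
  key <- if (by == "weighted") scores$weighted_score else scores$absolute_score
  out <- scores[order(-key, scores$fisher_p, scores$family_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Score and test every family of a screened cohort
#'
#' Combines the absolute, normalized and weighted scores with the Fisher
#' enrichment test.  The test margins are: genes in the family (across all
#' species), total genes in the family map, distinct downstream genes with a
#' candidate in the family, and distinct downstream genes with a candidate
#' overall.
#'
#' @inheritParams normalized_family_scores
#' @param bh Add a Benjamini-Hochberg adjusted p column (`fisher_padj`).
#' @return A ranked data frame (see [rank_families()]) with one row per
#'   family having at least one candidate.
#' @export
score_families <- function(candidates, family_map, species_order,
                           run_weight = 0.1,
                           mode = c("multiplicative", "additive"),
                           bh = FALSE) {
  mode <- match.arg(mode)
  if (!nrow(candidates))
    return(data.frame(family_id = character(0), n_genes_family = integer(0),
                      n_hit_family = integer(0), absolute_score = integer(0),
                      normalized_score = numeric(0),
                      weighted_score = numeric(0), fisher_p = numeric(0),
                      rank = integer(0)))
  abs_sc <- absolute_family_scores(candidates, family_map)
  norm_sc <- normalized_family_scores(candidates, family_map, species_order,
                                      run_weight, mode)
  fam <- candidate_families(candidates, family_map)
  hit_genes <- unique(candidates$downstream_gene_id)
  fam_sizes <- table(family_map$family_id)
  n_total <- nrow(family_map)
  n_hit_total <- length(hit_genes)
  fam_of_hit <- candidate_families(
    data.frame(downstream_gene_id = hit_genes, stringsAsFactors = FALSE),
    family_map)
  hits_per_fam <- table(fam_of_hit)
  out <- norm_sc
  out$n_genes_family <- as.integer(fam_sizes[out$family_id])
  out$n_hit_family <- as.integer(hits_per_fam[out$family_id])
  out$n_hit_family[is.na(out$n_hit_family)] <- 0L
  out$absolute_score <- as.integer(abs_sc[out$family_id])
  known <- !is.na(out$n_genes_family)
  out$fisher_p <- NA_real_  # genes outside the map are not testable
  out$fisher_p[known] <- fisher_enrichment(
    out$n_genes_family[known], n_total,
    pmin(out$n_hit_family[known], out$n_genes_family[known]), n_hit_total)
  if (bh) out$fisher_padj <- p.adjust(out$fisher_p, method = "BH")
  out <- out[, c("family_id", "n_genes_family", "n_hit_family",
                 "absolute_score", "normalized_score", "weighted_score",
                 "fisher_p", if (bh) "fisher_padj")]
  rank_families(out, by = "weighted")
}
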