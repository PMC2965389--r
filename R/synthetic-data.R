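# Synthetic multi-species cohorts with planted ground truth.
#
# The generator emulates the input structure the screen assumes: per species
# one linear replicon of iid background sequence, a few hundred genes with
# random strands separated by intergenic gaps, gene families assigned
# round-robin (so each family has a handful of paralogs per species), and a
# designated enriched family planted with 5' attenuators in a consecutive
# stretch of species.  Planted elements are written into the gaps with exact
# known geometry: 5' attenuators satisfying the screening filters, 3'
# terminators after (almost) every gene with a slightly longer mean stem so
# the 5'-vs-3' stability contrast has a known sign, labeled filter violators
# (distance / ratio / strand), and insertion-sequence cassettes sharing one
# conserved leader so mobile-attenuator clusters have known membership.
# Every output is reproducible from the spec's seed.

.safe_products <- c("ABC transporter ATP-binding protein",
                    "DNA polymerase III subunit beta",
                    "ribosomal protein L7/L12",
                    "aminotransferase class I",
                    "MFS family permease",
                    "two-component response regulator",
                    "glycosyltransferase family 2 protein",
                    "tRNA ligase beta subunit")

#' Specification for a synthetic screening cohort
#'
#' Defaults describe the reference validation cohort: 10 species of 300
#' genes, 60 families, GC 0.5 background, intergenic gaps of 50-400 nt, 200
#' planted 5' attenuators (stem 8 +/- 1 bp at GC 0.8, 12-T tails) including
#' 8 in consecutive species for one enriched family, a 3' terminator (stem
#' 9 +/- 1 bp) after every gene, 15 labeled filter violators and 6
#' insertion-sequence cassettes sharing one conserved leader.
#'
#' @param n_species,genes_per_species,n_families Cohort dimensions.
#' @param background_gc Background GC fraction.
#' @param intergenic_len,gene_len Length ranges (nt), `c(min, max)`.
#' @param n_plant_5p Number of planted 5' attenuators (including the
#'   enriched-family plants, excluding violators and IS cassettes).
#' @param stem_len_5p,stem_len_3p `c(mean, sd)` of planted stem lengths (bp),
#'   drawn rounded and clamped to 4-18.
#' @param stem_gc GC fraction of planted stems.
#' @param tail_t_count Number of T in the planted 12-nt tail.
#' @param plant_3p_all Plant a 3' terminator after every gene.
#' @param n_is_elements Number of insertion-sequence cassettes.
#' @param n_violators Named counts of labeled filter violators,
#'   `c(distance = , ratio = , strand = )`.
#' @param enriched_family Family id receiving consecutive-species plants
#'   (default the first family).
#' @param enriched_species Indices of the species planted for the enriched
#'   family (default the first 8, a consecutive stretch).
#' @param plant_5p Optional data frame (`family`, `species`) overriding the
#'   per-(family, species) planting plan.
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_species = 10L, genes_per_species = 300L,
                           n_families = 60L, background_gc = 0.5,
                           intergenic_len = c(50L, 400L),
                           gene_len = c(300L, 900L),
                           n_plant_5p = 200L,
                           stem_len_5p = c(8, 1), stem_len_3p = c(9, 1),
                           stem_gc = 0.8, tail_t_count = 12L,
                           plant_3p_all = TRUE, n_is_elements = 6L,
                           n_violators = c(distance = 5L, ratio = 5L,
                                           strand = 5L),
                           enriched_family = NULL, enriched_species = NULL,
                           plant_5p = NULL, seed = 1L) {
  stopifnot(background_gc >= 0, background_gc <= 1,
            stem_gc >= 0, stem_gc <= 1,
            stem_len_5p[1] >= 4, stem_len_5p[1] <= 18,
            stem_len_3p[1] >= 4, stem_len_3p[1] <= 18,
            tail_t_count >= 0, tail_t_count <= 12,
            n_species >= 1, genes_per_species >= 3, n_families >= 1)
  structure(list(
    n_species = as.integer(n_species),
    genes_per_species = as.integer(genes_per_species),
    n_families = as.integer(n_families),
    background_gc = background_gc,
    intergenic_len = as.integer(intergenic_len),
    gene_len = as.integer(gene_len),
    n_plant_5p = as.integer(n_plant_5p),
    stem_len_5p = stem_len_5p, stem_len_3p = stem_len_3p,
    stem_gc = stem_gc, tail_t_count = as.integer(tail_t_count),
    plant_3p_all = isTRUE(plant_3p_all),
    n_is_elements = as.integer(n_is_elements),
    n_violators = n_violators,
    enriched_family = enriched_family, enriched_species = enriched_species,
    plant_5p = plant_5p, seed = as.integer(seed)),
    class = "synthetic_spec")
}

# A terminator motif string with a 5' "C" clamp that cannot pair with the
# tail, so chance outward stem extension does not shift the planted
# geometry.  Layout: C | stem5 (L) | loop | stem3 (L) | spacer (A's) | tail.
#' @noRd
make_motif <- function(stem_len, stem_gc, tail_t, loop_len = 4L,
                       spacer_len = 0L) {
  s5 <- sample(c("G", "C", "A", "T"), stem_len, replace = TRUE,
               prob = c(stem_gc / 2, stem_gc / 2,
                        (1 - stem_gc) / 2, (1 - stem_gc) / 2))
  s3 <- rev(chartr("ACGT", "TGCA", s5))
  loop <- sample(c("A", "C", "G", "T"), loop_len, replace = TRUE)
  tail <- c(rep("T", tail_t),
            sample(c("A", "C", "G"), 12L - tail_t, replace = TRUE))
  motif <- paste(c("C", s5, loop, s3, rep("A", spacer_len), tail),
                 collapse = "")
  list(motif = motif, stem_len = stem_len, loop_len = loop_len,
       spacer_len = spacer_len,
       delta_g = hairpin_delta_g(paste(s5, collapse = ""),
                                 paste(s3, collapse = ""), loop_len))
}

#' Plant a terminator motif into a sequence
#'
#' Writes a stem-loop-stem + spacer + 12-nt tail motif (with a 1-nt 5' clamp)
#' into `seq` starting at `pos`, and returns the modified sequence together
#' with a truth record of the planted geometry.  Uses the current RNG stream.
#'
#' @param seq Character string to plant into.
#' @param pos 1-based start of the planted motif (clamp included).
#' @param stem_len Stem length in bp (4-18; shorter stems are refused
#'   because they could not be recovered as ground truth).
#' @param stem_gc GC fraction of the stem.
#' @param tail_t Number of T among the 12 tail positions (T's first).
#' @param loop_len,spacer_len Loop and spacer lengths.
#' @param occupied Optional list of previously planted `c(start, end)`
#'   intervals; overlap is an error.
#' @return A list: `seq` (modified), `truth` (data frame of planted
#'   coordinates on `seq`, scan orientation), `interval` (`c(start, end)`).
#' @export
plant_terminator <- function(seq, pos, stem_len, stem_gc = 0.8, tail_t = 12L,
                             loop_len = 4L, spacer_len = 0L, occupied = NULL) {
  if (stem_len < 4 || stem_len > 18)
    stop("stem_len must be within 4-18 for a plantable truth")
  if (loop_len < 3) stop("loop_len must be >= 3")
  m <- make_motif(stem_len, stem_gc, tail_t, loop_len, spacer_len)
  mlen <- nchar(m$motif)
  if (pos < 1 || pos + mlen - 1 > nchar(seq))
    stop("insufficient room to plant a ", mlen, " nt motif at position ", pos)
  for (iv in occupied)
    if (max(iv[1], pos) <= min(iv[2], pos + mlen - 1))
      stop("planting at position ", pos, " overlaps an existing plant")
  substr(seq, pos, pos + mlen - 1) <- m$motif
  truth <- motif_truth(pos, stem_len, loop_len, spacer_len, "+")
  truth$delta_g <- m$delta_g
  list(seq = seq, truth = truth, interval = c(pos, pos + mlen - 1))
}

# Forward-coordinate truth intervals for a motif whose (possibly
# reverse-complemented) string occupies [at, at + mlen - 1].
#' @noRd
motif_truth <- function(at, L, ll, sp, strand) {
  mlen <- 1L + 2L * L + ll + sp + 12L
  k <- function(from, to) {  # motif-internal 1-based positions -> forward
    if (strand == "+") c(at + from - 1L, at + to - 1L)
    else c(at + mlen - to, at + mlen - from)
  }
  s5 <- k(2L, L + 1L)
  lp <- k(L + 2L, L + ll + 1L)
  s3 <- k(L + ll + 2L, 2L * L + ll + 1L)
  tl <- k(mlen - 11L, mlen)
  data.frame(strand = strand, stem5_start = s5[1], stem5_end = s5[2],
             loop_start = lp[1], loop_end = lp[2],
             stem3_start = s3[1], stem3_end = s3[2], spacer_len = sp,
             tail_start = tl[1], tail_end = tl[2], stem_len = L,
             loop_len = ll, motif_start = at, motif_end = at + mlen - 1L,
             stringsAsFactors = FALSE)
}

#' @noRd
draw_stem_len <- function(ms) {
  max(4L, min(18L, as.integer(round(rnorm(1, ms[1], ms[2])))))
}

#' Generate a synthetic screening cohort with ground truth
#'
#' See [synthetic_spec()] for the cohort layout.  Returns in-memory genome
#' annotations plus the family map, species order and a truth table with one
#' row per planted element (`class` in `5p`, `3p`, `IS`; `violation` in
#' `none`, `distance`, `ratio`, `strand`; forward-coordinate motif
#' geometry; target gene and family; planted `d_down`/`d_up` for 5'
#' elements).  Two calls with the same spec give identical cohorts.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `attenuator_cohort`: `annotations` (named list of
#'   `genome_annotation`), `family_map`, `species_order`, `truth`, `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, generate_cohort_impl(spec))
}

#' @noRd
generate_cohort_impl <- function(spec) {
  ns <- spec$n_species
  ng <- spec$genes_per_species
  nf <- spec$n_families
  species <- sprintf("sp%02d", seq_len(ns))
  families <- sprintf("F%03d", seq_len(nf))
  enr_fam <- spec$enriched_family %||% families[1]
  enr_sp_idx <- spec$enriched_species %||% seq_len(min(8L, ns))

  # planting plan: one (family, species) cell per plant
  plan <- spec$plant_5p
  if (is.null(plan)) {
    plan <- data.frame(family = character(0), species = character(0))
    if (spec$n_plant_5p > 0) {
      enr <- data.frame(family = enr_fam, species = species[enr_sp_idx],
                        stringsAsFactors = FALSE)
      enr <- enr[seq_len(min(nrow(enr), spec$n_plant_5p)), , drop = FALSE]
      remaining <- spec$n_plant_5p - nrow(enr)
      # only families that actually receive genes under round-robin
      populated <- families[seq_len(min(nf, ng))]
      cells <- expand.grid(family = setdiff(populated, enr_fam),
                           species = species, stringsAsFactors = FALSE)
      if (remaining > nrow(cells))
        stop("n_plant_5p exceeds available (family, species) cells")
      extra <- cells[sample.int(nrow(cells), remaining), , drop = FALSE]
      plan <- rbind(enr, extra)
    }
  }

  # violator and IS cell assignment (species round-robin)
  nv <- spec$n_violators
  viol_dist_sp <- if (nv[["distance"]] > 0)
    species[((seq_len(nv[["distance"]]) - 1L) %% ns) + 1L] else character(0)
  viol_ratio_sp <- if (nv[["ratio"]] > 0)
    species[((seq_len(nv[["ratio"]]) - 1L) %% ns) + 1L] else character(0)
  viol_strand_sp <- if (nv[["strand"]] > 0)
    species[((seq_len(nv[["strand"]]) - 1L) %% ns) + 1L] else character(0)
  is_sp <- if (spec$n_is_elements > 0)
    species[((seq_len(spec$n_is_elements) - 1L) %% ns) + 1L] else character(0)

  # one conserved IS leader for the whole cohort: 60 nt context + motif
  is_motif <- make_motif(10L, 0.85, 12L, loop_len = 4L, spacer_len = 0L)
  is_leader <- paste0(random_dna(60, spec$background_gc), is_motif$motif)

  anns <- list()
  truth_rows <- list()
  fam_rows <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    glen <- sample(seq(spec$gene_len[1], spec$gene_len[2]), ng,
                   replace = TRUE)
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    fam <- families[((seq_len(ng) - 1L) %% nf) + 1L]
    prods <- sample(.safe_products, ng, replace = TRUE)
    gene_ids <- sprintf("%s_g%04d", sp, seq_len(ng))

    special <- integer(0)  # gene indices reserved by violators / IS
    viol_genes <- list(distance = integer(0), ratio = integer(0),
                       strand = integer(0))
    n_vd <- sum(viol_dist_sp == sp)
    if (n_vd > 0) {  # at most one start-of-replicon violator per species
      viol_genes$distance <- 1L
      strand[1] <- "+"
      special <- c(special, 1L)
    }
    pick_pair <- function(k) {
      # genes t with a free (t-1, t) pair, both forced "+"
      avail <- setdiff(3:ng, c(special, special + 1L, special - 1L))
      if (length(avail) < k) stop("layout infeasible: too many special genes")
      sort(avail[sample.int(length(avail), k)])
    }
    if (sum(viol_ratio_sp == sp) > 0) {
      t <- pick_pair(sum(viol_ratio_sp == sp))
      viol_genes$ratio <- t
      strand[t] <- "+"; strand[t - 1L] <- "+"
      special <- c(special, t, t - 1L)
    }
    if (sum(viol_strand_sp == sp) > 0) {
      t <- pick_pair(sum(viol_strand_sp == sp))
      viol_genes$strand <- t
      strand[t] <- "+"; strand[t - 1L] <- "+"
      special <- c(special, t, t - 1L)
    }
    is_genes <- integer(0)
    n_is <- sum(is_sp == sp)
    if (n_is > 0) {
      avail <- setdiff(3:ng, c(special, special + 1L, special - 1L))
      is_genes <- sort(avail[sample.int(length(avail), n_is)])
      strand[is_genes] <- "+"
      prods[is_genes] <- "IS3 family transposase"
      fam[is_genes] <- "F_IS"
      special <- c(special, is_genes)
    }

    # resolve the planting plan to gene indices
    att5 <- logical(ng)
    for (f in plan$family[plan$species == sp]) {
      cand_idx <- setdiff(which(fam == f & !att5), special)
      if (!length(cand_idx))
        stop("layout infeasible: no free gene of family ", f, " in ", sp)
      att5[cand_idx[sample.int(length(cand_idx), 1L)]] <- TRUE
    }

    built <- build_species_sequence(
      sp, glen, strand, fam, prods, gene_ids, att5, viol_genes, is_genes,
      is_leader, is_motif, spec)
    anns[[sp]] <- built$ann
    truth_rows[[sp]] <- built$truth
    fam_rows[[sp]] <- data.frame(gene_id = gene_ids, species_id = sp,
                                 family_id = fam, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  if (is.null(truth))
    truth <- cbind(motif_truth(1L, 4L, 3L, 0L, "+")[0, ],
                   data.frame(delta_g = numeric(0),
                              species_id = character(0),
                              replicon_id = character(0),
                              class = character(0), violation = character(0),
                              target_gene_id = character(0),
                              family_id = character(0), d_down = integer(0),
                              d_up = integer(0)))
  rownames(truth) <- NULL
  if (nrow(truth))
    truth$element_id <- sprintf("el%04d", seq_len(nrow(truth)))
  else truth$element_id <- character(0)
  structure(list(annotations = anns,
                 family_map = do.call(rbind, fam_rows),
                 species_order = species, truth = truth, spec = spec),
            class = "attenuator_cohort")
}

# Assemble one species: alternating gaps and genes, with planted elements
# written into the gaps at exact local coordinates.
#' @noRd
build_species_sequence <- function(sp, glen, strand, fam, prods, gene_ids,
                                   att5, viol_genes, is_genes, is_leader,
                                   is_motif, spec) {
  ng <- length(glen)
  repid <- paste0(sp, "_chr")
  segs <- character(0)
  cursor <- 0L
  truth <- list()
  gstart <- gend <- integer(ng)
  ig <- spec$intergenic_len

  add_truth <- function(tr_local, offset, class, violation, gene_idx,
                        d_down = NA_integer_, d_up = NA_integer_,
                        delta_g = NA_real_) {
    tr <- tr_local
    for (col in c("stem5_start", "stem5_end", "loop_start", "loop_end",
                  "stem3_start", "stem3_end", "tail_start", "tail_end",
                  "motif_start", "motif_end"))
      tr[[col]] <- tr[[col]] + offset
    tr$species_id <- sp
    tr$replicon_id <- repid
    tr$class <- class
    tr$violation <- violation
    tr$target_gene_id <- if (is.na(gene_idx)) NA_character_
                         else gene_ids[gene_idx]
    tr$family_id <- if (is.na(gene_idx)) NA_character_ else fam[gene_idx]
    tr$d_down <- d_down
    tr$d_up <- d_up
    tr$delta_g <- delta_g
    truth[[length(truth) + 1L]] <<- tr
  }

  for (i in seq_len(ng + 1L)) {
    left <- if (i > 1L) i - 1L else NA_integer_
    right <- if (i <= ng) i else NA_integer_

    # ---- decide the gap's elements ----
    left_el <- NULL
    if (!is.na(left)) {
      if (strand[left] == "+" && spec$plant_3p_all)
        left_el <- list(type = "term3", strand = "+", gene = left)
      else if (strand[left] == "-" && att5[left])
        left_el <- list(type = "att5", strand = "-", gene = left)
    }
    right_el <- NULL
    if (!is.na(right)) {
      if (right %in% is_genes)
        right_el <- list(type = "is", strand = "+", gene = right)
      else if (strand[right] == "+" &&
               (att5[right] || right %in% viol_genes$distance ||
                right %in% viol_genes$ratio))
        right_el <- list(type = "att5", strand = "+", gene = right,
                         violation = if (right %in% viol_genes$distance)
                           "distance"
                         else if (right %in% viol_genes$ratio) "ratio"
                         else "none")
      else if (strand[right] == "-" && spec$plant_3p_all)
        right_el <- list(type = "term3", strand = "-", gene = right)
    }
    mid_el <- if (!is.na(right) && right %in% viol_genes$strand)
      list(type = "strandviol", gene = right) else NULL

    # ---- build motifs and compute needs ----
    mk5 <- function() make_motif(draw_stem_len(spec$stem_len_5p),
                                 spec$stem_gc, spec$tail_t_count,
                                 loop_len = 4L,
                                 spacer_len = sample(0:2, 1L))
    mk3 <- function() make_motif(draw_stem_len(spec$stem_len_3p),
                                 spec$stem_gc, spec$tail_t_count,
                                 loop_len = 4L,
                                 spacer_len = sample(0:2, 1L))
    L_need <- 0L
    if (!is.null(left_el)) {
      if (left_el$type == "term3") {
        left_el$off3 <- sample(5:15, 1L)
        left_el$m <- mk3()
        L_need <- left_el$off3 + nchar(left_el$m$motif)
      } else {
        left_el$m <- mk5()
        left_el$d_down <- sample(25:90, 1L)
        L_need <- left_el$d_down + nchar(left_el$m$motif)
      }
    }
    R_need <- 0L
    if (!is.null(right_el)) {
      if (right_el$type == "term3") {
        right_el$off3 <- sample(5:15, 1L)
        right_el$m <- mk3()
        R_need <- right_el$off3 + nchar(right_el$m$motif)
      } else if (right_el$type == "is") {
        right_el$d_down <- 25L
        R_need <- right_el$d_down + nchar(is_leader)
      } else {
        right_el$m <- mk5()
        right_el$d_down <- switch(right_el$violation,
                                  distance = sample(305:340, 1L),
                                  ratio = NA_integer_,  # set below
                                  sample(25:90, 1L))
        if (right_el$violation == "ratio") {
          right_el$d_up_target <- L_need + sample(8:18, 1L)
          right_el$d_down <- min(right_el$d_up_target + sample(40:80, 1L),
                                 295L)
        }
        R_need <- right_el$d_down + nchar(right_el$m$motif)
      }
    }
    mid_need <- 0L
    if (!is.null(mid_el)) {
      mid_el$m <- mk5()
      mid_need <- nchar(mid_el$m$motif) + 20L
    }

    # ---- size the gap ----
    G <- sample(seq(ig[1], ig[2]), 1L)
    G <- max(G, L_need + R_need + mid_need + 10L)
    su <- function(el, need_other) {
      # enforce d_up >= d_down for passing att5 plants
      if (!is.null(el) && el$type == "att5" &&
          identical(el$violation %||% "none", "none"))
        2L * el$d_down + nchar(el$m$motif) + 5L + need_other
      else if (!is.null(el) && el$type == "att5" &&
               identical(el$violation, "ratio"))
        -1L  # handled exactly below
      else 0L
    }
    G <- max(G, su(right_el, L_need + mid_need))
    if (!is.null(left_el) && left_el$type == "att5")
      G <- max(G, 2L * left_el$d_down + nchar(left_el$m$motif) + 5L +
                 R_need + mid_need)
    if (!is.null(right_el) && identical(right_el$violation %||% "none",
                                        "ratio"))
      G <- right_el$d_up_target + nchar(right_el$m$motif) +
        right_el$d_down - 1L

    # ---- assemble the gap ----
    gap <- random_dna(G, spec$background_gc)
    place <- function(gap, at, motif_str) {
      substr(gap, at, at + nchar(motif_str) - 1L) <- motif_str
      gap
    }
    if (!is.null(left_el)) {
      if (left_el$type == "term3") {
        at <- left_el$off3 + 1L
        gap <- place(gap, at, left_el$m$motif)
        tr <- motif_truth(at, left_el$m$stem_len, left_el$m$loop_len,
                          left_el$m$spacer_len, "+")
        add_truth(tr, cursor, "3p", "none", left_el$gene,
                  delta_g = left_el$m$delta_g)
      } else {
        mlen <- nchar(left_el$m$motif)
        at <- left_el$d_down + 1L
        gap <- place(gap, at, revcomp(left_el$m$motif))
        tr <- motif_truth(at, left_el$m$stem_len, left_el$m$loop_len,
                          left_el$m$spacer_len, "-")
        d_up <- G - (at + mlen - 1L) + 1L
        add_truth(tr, cursor, "5p", "none", left_el$gene,
                  d_down = left_el$d_down, d_up = d_up,
                  delta_g = left_el$m$delta_g)
      }
    }
    if (!is.null(right_el)) {
      if (right_el$type == "term3") {
        mlen <- nchar(right_el$m$motif)
        at <- G - right_el$off3 - mlen + 1L
        gap <- place(gap, at, revcomp(right_el$m$motif))
        tr <- motif_truth(at, right_el$m$stem_len, right_el$m$loop_len,
                          right_el$m$spacer_len, "-")
        add_truth(tr, cursor, "3p", "none", right_el$gene,
                  delta_g = right_el$m$delta_g)
      } else if (right_el$type == "is") {
        at <- G - right_el$d_down - nchar(is_leader) + 1L
        gap <- place(gap, at, is_leader)
        m_at <- at + 60L  # motif begins after the conserved context
        tr <- motif_truth(m_at, is_motif$stem_len, is_motif$loop_len,
                          is_motif$spacer_len, "+")
        d_up <- m_at
        add_truth(tr, cursor, "IS", "none", right_el$gene,
                  d_down = right_el$d_down, d_up = d_up,
                  delta_g = is_motif$delta_g)
      } else {
        mlen <- nchar(right_el$m$motif)
        at <- G - right_el$d_down - mlen + 1L
        gap <- place(gap, at, right_el$m$motif)
        tr <- motif_truth(at, right_el$m$stem_len, right_el$m$loop_len,
                          right_el$m$spacer_len, "+")
        d_up <- if (i == 1L) NA_integer_ else at
        add_truth(tr, cursor, "5p", right_el$violation, right_el$gene,
                  d_down = right_el$d_down, d_up = d_up,
                  delta_g = right_el$m$delta_g)
      }
    }
    if (!is.null(mid_el)) {
      at <- L_need + 15L  # clear of both gap-end elements
      gap <- place(gap, at, revcomp(mid_el$m$motif))
      tr <- motif_truth(at, mid_el$m$stem_len, mid_el$m$loop_len,
                        mid_el$m$spacer_len, "-")
      add_truth(tr, cursor, "5p", "strand", mid_el$gene,
                delta_g = mid_el$m$delta_g)
    }

    segs <- c(segs, gap)
    cursor <- cursor + G
    if (!is.na(right)) {
      gstart[right] <- cursor + 1L
      gend[right] <- cursor + glen[right]
      segs <- c(segs, random_dna(glen[right], spec$background_gc))
      cursor <- cursor + glen[right]
    }
  }

  genome <- paste(segs, collapse = "")
  genes <- data.frame(gene_id = gene_ids, replicon_id = repid,
                      start = gstart, end = gend, strand = strand,
                      product = prods, stringsAsFactors = FALSE)
  reps <- Biostrings::DNAStringSet(setNames(genome, repid))
  ann <- genome_annotation(sp, reps, genes, topology = "linear")
  tr <- if (length(truth)) do.call(rbind, truth) else NULL
  list(ann = ann, truth = tr)
}

#' Write a cohort to disk (FASTA, GFF3, TSV)
#'
#' Emits, per species, `<sp>.fasta` and `<sp>.gff3`, plus `family_map.tsv`,
#' `species_order.txt` and `truth.tsv`.  Byte-identical for identical specs.
#'
#' @param cohort An `attenuator_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(cohort$annotations)) {
    ann <- cohort$annotations[[sp]]
    Biostrings::writeXStringSet(ann$replicons,
                                file.path(dir, paste0(sp, ".fasta")))
    g <- ann$genes
    gr <- GenomicRanges::GRanges(
      seqnames = g$replicon_id,
      ranges = IRanges::IRanges(start = g$start, end = g$end),
      strand = g$strand)
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- g$gene_id
    S4Vectors::mcols(gr)$product <- g$product
    rtracklayer::export(gr, file.path(dir, paste0(sp, ".gff3")),
                        format = "gff3")
  }
  write.table(cohort$family_map, file.path(dir, "family_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(cohort$species_order, file.path(dir, "species_order.txt"))
  write.table(cohort$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Match screened candidates against a planted truth table
#'
#' A candidate matches a planted element when species, replicon and strand
#' agree and the tail 3' ends lie within `tol` nucleotides (chance stem
#' extension into the background can shift a detection by a base or two).
#' Sensitivity is computed over filter-passing planted 5' elements (classes
#' `5p` with `violation == "none"`, plus `IS`); precision over all emitted
#' candidates.
#'
#' @param candidates Combined candidates (from [screen_cohort()]).
#' @param truth Cohort truth table.
#' @param tol Tail-end matching tolerance (nt).
#' @details Sensitivity asks whether the intended targets were recovered:
#'   it is computed over the filter-passing planted 5' elements (classes
#'   `5p`/`IS`, `violation == "none"`).  Precision asks whether emitted
#'   candidates are real planted terminators rather than chance background
#'   hits, so a candidate also counts as true when it matches a planted 3'
#'   terminator: in a short gap a 3' terminator can satisfy every
#'   orientation/distance criterion of an attenuator and is then, by the
#'   method's own definition, indistinguishable from one.
#' @return A list: `sensitivity`, `precision`, `n_truth`, `n_candidates`,
#'   `n_matched_truth`, `n_matched_candidates`, plus per-row logicals
#'   `truth_detected` and `candidate_matched` (match against any
#'   non-violator planted element).
#' @export
evaluate_detection <- function(candidates, truth, tol = 3L) {
  tail3p <- function(x) ifelse(x$strand == "+", x$tail_end, x$tail_start)
  keys <- function(x) paste(x$species_id, x$replicon_id, x$strand)
  match_any <- function(qk, qt, tk, tt)
    vapply(seq_along(qk), function(i)
      any(tk == qk[i] & abs(tt - qt[i]) <= tol), logical(1))
  pos5 <- truth[truth$class %in% c("5p", "IS") & truth$violation == "none", ,
                drop = FALSE]
  planted <- truth[truth$violation == "none", , drop = FALSE]
  truth_detected <- match_any(keys(pos5), tail3p(pos5),
                              keys(candidates), tail3p(candidates))
  cand_matched <- match_any(keys(candidates), tail3p(candidates),
                            keys(planted), tail3p(planted))
  list(sensitivity = mean(truth_detected),
       precision = if (nrow(candidates)) mean(cand_matched) else NA_real_,
       n_truth = nrow(pos5), n_candidates = nrow(candidates),
       n_matched_truth = sum(truth_detected),
       n_matched_candidates = sum(cand_matched),
       truth_detected = truth_detected, candidate_matched = cand_matched)
}
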