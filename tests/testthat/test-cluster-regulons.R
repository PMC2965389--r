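# Alignment scores, distances, clustering, cluster classes, mobile flags.

test_that("lambda solves the Karlin-Altschul identity numerically", {
  sc <- align_scoring()
  p <- 0.25
  lhs <- (4 * p^2) * exp(sc$lambda * sc$match) +
    (12 * p^2) * exp(sc$lambda * sc$mismatch)
  expect_equal(lhs, 1, tolerance = 1e-9)
})

test_that("identical sequences score by the bit conversion formula", {
  sc <- align_scoring()
  a <- strrep("ACGT", 25)
  raw <- 100 * sc$match
  expect_equal(local_alignment_score(a, a, sc),
               (sc$lambda * raw - log(sc$K)) / log(2))
  expect_equal(local_alignment_score(strrep("A", 50), strrep("C", 50), sc),
               0)
})

test_that("alignment scores equal the independent DP oracle and commute", {
  set.seed(808)
  sc <- align_scoring()
  for (i in 1:40) {
    a <- rand_dna(40)
    b <- if (i %% 3 == 0) paste0(rand_dna(10), substr(a, 5, 30),
                                 rand_dna(10)) else rand_dna(40)
    raw <- oracle_sw_raw(a, b)
    want <- if (raw <= 0) 0 else (sc$lambda * raw - log(sc$K)) / log(2)
    expect_equal(local_alignment_score(a, b, sc), want, tolerance = 1e-9,
                 info = paste(a, b))
    expect_equal(local_alignment_score(a, b, sc),
                 local_alignment_score(b, a, sc), tolerance = 1e-9)
  }
})

test_that("distances invert bit scores with a cap and the 0.038 boundary", {
  expect_equal(1 / 26.3, 0.038, tolerance = 1e-3)
  set.seed(9)
  leaders <- c(a = rand_dna(150), b = rand_dna(150), c = rand_dna(150))
  leaders["b"] <- leaders[["a"]]  # identical pair
  dm <- pairwise_distance_matrix(leaders, cap = 1)
  expect_true(isSymmetric(unclass(dm)))
  expect_equal(unname(diag(dm)), c(0, 0, 0))
  expect_lt(dm["a", "b"], 0.038)
  expect_equal(dm["a", "b"], min(dm[upper.tri(dm)]))
  # unrelated random pairs never fall below the cut, never exceed the cap
  expect_gt(dm["a", "c"], 0.038)
  expect_lte(dm["a", "c"], 1)
  # sequences with no positive-scoring alignment sit exactly at the cap
  dm2 <- pairwise_distance_matrix(c(x = strrep("A", 50),
                                    y = strrep("C", 50)), cap = 1)
  expect_equal(unname(dm2["x", "y"]), 1)
})

test_that("clustering cuts at the boundary height inclusively", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.038   # exactly the cut height
  d["c", "d"] <- d["d", "c"] <- 0.039   # just above
  cs <- cluster_and_cut(d)
  expect_equal(cs$membership[["a"]], cs$membership[["b"]])
  expect_false(cs$membership[["c"]] == cs$membership[["d"]])
  # all-cap matrix: all singletons
  d2 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d2) <- 0
  expect_equal(length(cluster_and_cut(d2)$clusters), 3L)
})

test_that("complete-linkage merge heights never invert", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(paste0("x", 1:n), paste0("x", 1:n))
    cs <- cluster_and_cut(m)
    expect_true(all(diff(cs$tree$height) >= -1e-12))
  }
})

test_that("clustering is invariant under candidate relabeling", {
  set.seed(15)
  leaders <- setNames(c(rand_dna(120), rand_dna(120), rand_dna(120),
                        rand_dna(120)), paste0("L", 1:4))
  leaders[2] <- leaders[[1]]
  cs1 <- cluster_and_cut(pairwise_distance_matrix(leaders))
  perm <- c(3, 1, 4, 2)
  leaders2 <- setNames(leaders[perm], paste0("M", 1:4))
  cs2 <- cluster_and_cut(pairwise_distance_matrix(leaders2))
  part <- function(cs, nm) {
    key <- split(nm, cs$membership[names(cs$membership)])
    unname(lapply(key, sort))
  }
  orig_names <- paste0("L", 1:4)
  p1 <- part(cs1, orig_names)
  p2 <- part(cs2, orig_names[perm])
  expect_setequal(vapply(p1, paste, "", collapse = ","),
                  vapply(p2, paste, "", collapse = ","))
})

test_that("cluster classes a/b/c follow the family composition rule", {
  expect_equal(classify_cluster(c("F1", "F1", "F1")), "a")
  expect_equal(classify_cluster(c("F1", "F2", "F3")), "b")
  expect_equal(classify_cluster(c("F1", "F1", "F2", "F2")), "c")
  expect_equal(classify_cluster(c("F1", "F1", "F2")), "b")
  expect_equal(classify_cluster("F1"), "a")
})

test_that("mobile flags trigger on IS-related products only", {
  expect_true(flag_mobile("IS3 family transposase"))
  expect_true(flag_mobile(c("ABC transporter", "phage integrase")))
  expect_false(flag_mobile(c("ABC transporter permease", "kinase")))
})

test_that("planted IS leaders co-cluster, class a, flagged mobile", {
  fix <- small_cohort_screen()
  coh <- fix$cohort
  scr <- fix$screen
  cands <- scr$candidates
  rc <- cluster_leaders(cands, coh$family_map, coh$annotations)
  is_truth <- coh$truth[coh$truth$class == "IS", ]
  # candidates at the planted IS positions
  tailc <- ifelse(cands$strand == "+", cands$tail_end, cands$tail_start)
  is_ids <- cands$candidate_id[vapply(seq_len(nrow(cands)), function(j)
    any(is_truth$species_id == cands$species_id[j] &
          abs(ifelse(is_truth$strand == "+", is_truth$tail_end,
                     is_truth$tail_start) - tailc[j]) <= 3), logical(1))]
  expect_equal(length(is_ids), nrow(is_truth))
  memb <- rc$cluster_set$membership[is_ids]
  expect_equal(length(unique(memb)), 1L)  # one shared-leader cluster
  cl <- rc$clusters[rc$clusters$cluster == paste0("cluster", memb[1]), ]
  expect_equal(cl$class, "a")
  expect_true(cl$mobile)
  others <- rc$clusters[rc$clusters$cluster != paste0("cluster", memb[1]), ]
  expect_true(all(!others$mobile, na.rm = TRUE))
})
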