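# BFS over a bond list: independent check of the distance-based levels.
bfs_within <- function(bonds, start, radius, n_atoms) {
  adj <- vector("list", n_atoms)
  for (b in bonds) {
    i <- b[[1]] + 1L; j <- b[[2]] + 1L
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  dist <- rep(Inf, n_atoms); dist[start] <- 0
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (dist[w] > dist[v] + 1) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      }
    }
    frontier <- nxt
  }
  sort(which(dist <= radius))
}

test_that("fragment levels equal a breadth-first-search oracle and nest", {
  smi <- "OC(=O)c1ccccc1"
  lv <- fragment_from_anchor(smi)[[1]]
  raw <- molrules:::run_fragment_helper(smi)[[1]]
  anchor <- raw$anchor + 1L
  bonds <- raw$bonds
  for (k in 1:3) {
    expect_equal(lv[[k]], bfs_within(bonds, anchor, c(2, 4, 6)[k], raw$n_atoms))
  }
  expect_true(all(lv[[1]] %in% lv[[2]]))
  expect_true(all(lv[[2]] %in% lv[[3]]))
  # small molecule saturates every level
  lv_small <- fragment_from_anchor("CC(=O)O")[[1]]
  expect_equal(lengths(lv_small), c(4L, 4L, 4L))
  expect_error(fragment_from_anchor("CCO"), "carboxyl")
})

test_that("levels are nested for many generated acids", {
  set.seed(101)
  chains <- vapply(1:100, function(i) {
    paste0("OC(=O)C", paste(sample(c("C", "N", "O"), sample(1:6, 1),
                                   replace = TRUE), collapse = ""))
  }, character(1))
  lvs <- fragment_from_anchor(chains)
  for (lv in lvs) {
    expect_true(all(lv[[1]] %in% lv[[2]]) && all(lv[[2]] %in% lv[[3]]))
  }
})

test_that("pooled means match an explicit per-atom loop", {
  smi <- "OC(=O)c1ccccc1"
  raw <- molrules:::run_fragment_helper(smi)[[1]]
  lv1 <- fragment_from_anchor(smi)[[1]][[1]]
  row <- pooled_descriptors(smi)
  for (p in c("PEOE_charge", "LogP", "MR", "LabuteASA", "TPSA")) {
    vals <- unlist(raw$props[[p]])
    manual <- sum(vals[lv1]) / length(lv1)
    expect_equal(row[[paste0(p, "_L1")]], manual, info = p)
  }
})

test_that("whole-molecule fragment level recovers standard TPSA", {
  mols <- c("CC(=O)O", "OC(=O)c1ccccc1", "Nc1ccc(C(=O)O)cc1", "NCC(=O)O")
  ref <- rdkit_tpsa(mols)
  for (i in seq_along(mols)) {
    row <- pooled_descriptors(mols[i], radii = c(2, 4, 99))
    n_atoms <- molrules:::run_fragment_helper(mols[i],
                                              radii = c(2, 4, 99))[[1]]$n_atoms
    expect_equal(row[["TPSA_L3"]] * n_atoms, ref[i], tolerance = 1e-6)
  }
})

test_that("descriptor rows are invariant to input atom ordering", {
  a <- pooled_descriptors("OC(=O)c1ccc(N)cc1")
  b <- pooled_descriptors("Nc1ccc(C(=O)O)cc1")
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("correlation pruning drops duplicates and keeps independents", {
  set.seed(12)
  tab <- data.frame(a = rnorm(100), b = rnorm(100))
  tab$a_copy <- tab$a
  keep <- prune_correlated(tab)
  expect_equal(as.character(keep), c("a", "b"))
  expect_true("a_copy" %in% attr(keep, "dropped")$feature)

  # independent random columns survive across seeds
  for (s in 1:20) {
    set.seed(300 + s)
    ind <- as.data.frame(matrix(rnorm(100 * 5), 100, 5))
    kept <- prune_correlated(ind)
    expect_equal(as.character(kept), names(ind))
  }

  # zero-variance columns dropped with a diagnostic; order preserved
  tab2 <- data.frame(x = rnorm(50), flat = 1, y = rnorm(50))
  k2 <- prune_correlated(tab2)
  expect_equal(as.character(k2), c("x", "y"))
  expect_equal(attr(k2, "dropped")$reason, "zero variance")
})

test_that("descriptor table covers a dataset with 15 finite columns", {
  ds <- example_modifier_dataset()
  tab <- fragment_descriptor_table(ds)
  expect_equal(nrow(tab), 12)
  expect_equal(ncol(tab), 16)  # id + 5 properties x 3 levels
  expect_true(all(is.finite(as.matrix(tab[, -1]))))
})
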