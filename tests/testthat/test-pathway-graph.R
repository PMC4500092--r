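test_that("functional classification applies both criteria strictly", {
  fx <- pathway_fixtures()
  # uniform landscape: strict > grand mean fails everywhere
  calls <- classify_functional(fx$none_functional$landscape)
  expect_equal(sum(calls$functional), 0L)
  # a protein's best target always passes the fold criterion
  ls <- random_mean_landscape(1)
  calls <- classify_functional(ls)
  expect_true(all(!calls$outside_fold[calls$is_best_target]))
  # cutoff is RT ln(10) = 1.364 kcal/mol below the best target
  jg <- enumerate_joint_genotypes()
  ls2 <- data.frame(protein = jg$protein, re = jg$re, mean_dG = 8)
  ls2$mean_dG[ls2$protein == "glu-gly-ala" & ls2$re == "GT"] <- 12
  ls2$mean_dG[ls2$protein == "glu-gly-ala" & ls2$re == "GA"] <- 10.5  # 1.5 below best
  ls2$mean_dG[ls2$protein == "glu-gly-ala" & ls2$re == "GG"] <- 11.0  # 1.0 below best
  calls2 <- classify_functional(ls2)
  get <- function(re) calls2$functional[calls2$protein == "glu-gly-ala" &
                                        calls2$re == re]
  expect_false(get("GA"))   # above grand mean but outside the tenfold window
  expect_true(get("GG"))    # within 1.364 of best and above grand mean
  expect_error(classify_functional(ls[-1, ]), "incomplete landscape")
})

test_that("joint graph edges connect functional complexes one move apart", {
  fx <- pathway_fixtures()
  g <- build_joint_graph(fx$all_functional_calls$calls)
  expect_equal(igraph::vcount(g), 128L)
  expect_equal(igraph::ecount(g), 576L)   # 128 * 9 / 2
  expect_setequal(unique(igraph::E(g)$move_type), c("protein", "re"))
  # empty graph when nothing is functional
  g0 <- build_joint_graph(fx$none_functional$landscape)
  expect_equal(igraph::vcount(g0), 0L)
  # removing one functional node removes exactly its incident edges
  calls <- fx$all_functional_calls$calls
  victim <- which(calls$protein == "glu-gly-ala" & calls$re == "GT")
  calls$functional[victim] <- FALSE
  g1 <- build_joint_graph(calls)
  expect_equal(igraph::ecount(g1), 576L - 9L)
})

test_that("protein trajectory accessibility matches the fixture structure", {
  fx <- pathway_fixtures()
  tr <- protein_trajectories(fx$every_protein_functional$landscape)
  expect_equal(tr$n_accessible, 6L)
  tr0 <- protein_trajectories(fx$none_functional$landscape)
  expect_equal(tr0$n_accessible, 0L)
  sg <- protein_trajectories(fx$single_gateway$landscape)
  acc <- sg$orderings[sg$orderings$accessible, "ordering"]
  expect_gt(length(acc), 0L)
  expect_true(all(startsWith(acc, "site25")))
})

test_that("joint paths handle trivial and disconnected cases", {
  fx <- pathway_fixtures()
  calls <- classify_functional(fx$permissive_4node$landscape)
  # source in targets: length-0 path
  jp0 <- joint_paths(calls, "glu-gly-ala:GT", "glu-gly-ala:GT")
  expect_true(jp0$connected)
  expect_equal(jp0$shortest_length, 0L)
  # reachable target two moves away
  jp <- joint_paths(calls, "glu-gly-ala:GT", "GLY-gly-ala:TT")
  expect_true(jp$connected)
  expect_equal(jp$shortest_length, 2L)
  expect_equal(jp$paths[[1]],
               c("glu-gly-ala:GT", "GLY-gly-ala:GT", "GLY-gly-ala:TT"))
  # isolated functional source is disconnected from elsewhere
  jg <- enumerate_joint_genotypes()
  ls <- data.frame(protein = jg$protein, re = jg$re, mean_dG = 8)
  ls$mean_dG[ls$protein == "glu-gly-ala" & ls$re == "GT"] <- 12
  ls$mean_dG[ls$protein == "GLY-SER-VAL" & ls$re == "AA"] <- 12
  calls2 <- classify_functional(ls)
  jp2 <- joint_paths(calls2, "glu-gly-ala:GT", "GLY-SER-VAL:AA")
  expect_false(jp2$connected)
  expect_error(joint_paths(calls2, "glu-gly-ala:AA", "GLY-SER-VAL:AA"),
               "not functional")
})

test_that("path connectivity equals an exhaustive BFS oracle on random landscapes", {
  pg <- enumerate_protein_genotypes()$label
  for (seed in 1:25) {
    ls <- random_mean_landscape(seed)
    calls <- classify_functional(ls)
    fun <- paste0(calls$protein, ":", calls$re)[calls$functional]
    if (length(fun) < 2) next
    src <- fun[1]
    tgt <- fun[length(fun)]
    jp <- joint_paths(calls, src, tgt)
    oracle <- oracle_bfs(fun, src, tgt)
    expect_equal(jp$connected, oracle$connected)
    expect_equal(jp$shortest_length, oracle$shortest)
  }
})

test_that("raising the fold factor never shrinks the neutral graph", {
  ls <- random_mean_landscape(77)
  g10 <- build_joint_graph(classify_functional(ls, functional_criteria(fold = 10)))
  g100 <- build_joint_graph(classify_functional(ls, functional_criteria(fold = 100)))
  expect_true(all(igraph::V(g10)$name %in% igraph::V(g100)$name))
  e10 <- apply(igraph::as_data_frame(g10)[, 1:2], 1, function(r)
    paste(sort(r), collapse = "|"))
  e100 <- apply(igraph::as_data_frame(g100)[, 1:2], 1, function(r)
    paste(sort(r), collapse = "|"))
  expect_true(all(e10 %in% e100))
})

test_that("gating calls satisfy their definitional admissibility conditions", {
  fx <- pathway_fixtures()
  # separable functional set: no cross-molecule gating at all
  gs <- gating_analysis(fx$separable$landscape)
  expect_equal(sum(gs$cross_molecule), 0L)
  # hand-built permissive case is reported
  gr <- gating_analysis(fx$permissive_4node$landscape)
  hit <- gr[gr$context == "glu-gly-ala:GT" & gr$type == "permissive" &
            gr$gate_site == "site25" & gr$focal_molecule == "re" &
            gr$focal_site == "3" & gr$focal_to == "T", ]
  expect_equal(nrow(hit), 1L)
  # every reported event re-verified from the functional calls
  ls <- random_mean_landscape(13)
  calls <- classify_functional(ls)
  is_fun <- stats::setNames(calls$functional, paste0(calls$protein, ":", calls$re))
  rep <- gating_analysis(calls)
  apply_move <- function(protein, re, molecule, site, to) {
    if (molecule == "protein") {
      parts <- strsplit(protein, "-")[[1]]
      idx <- match(site, c("site25", "site26", "site29"))
      parts[idx] <- to
      list(protein = paste(parts, collapse = "-"), re = re)
    } else {
      idx <- match(site, c("3", "4"))
      substr(re, idx, idx) <- to
      list(protein = protein, re = re)
    }
  }
  check_rows <- rep[sample(nrow(rep), min(nrow(rep), 50)), ]
  for (i in seq_len(nrow(check_rows))) {
    r <- check_rows[i, ]
    g <- strsplit(r$context, ":", fixed = TRUE)[[1]]
    gm <- apply_move(g[1], g[2], r$gate_molecule, r$gate_site, r$gate_to)
    before <- apply_move(g[1], g[2], r$focal_molecule, r$focal_site, r$focal_to)
    after <- apply_move(gm$protein, gm$re, r$focal_molecule, r$focal_site,
                        r$focal_to)
    ok_before <- unname(is_fun[paste0(before$protein, ":", before$re)])
    ok_after <- unname(is_fun[paste0(after$protein, ":", after$re)])
    expect_true(unname(is_fun[r$context]))
    expect_true(unname(is_fun[paste0(gm$protein, ":", gm$re)]))
    if (r$type == "permissive") {
      expect_false(ok_before); expect_true(ok_after)
    } else {
      expect_true(ok_before); expect_false(ok_after)
    }
  }
})

test_that("reports are deterministic for identical landscapes", {
  ls <- random_mean_landscape(55)
  a <- protein_trajectories(ls)
  b <- protein_trajectories(ls)
  expect_identical(a$orderings, b$orderings)
  ga <- gating_analysis(ls)
  gb <- gating_analysis(ls)
  expect_identical(as.data.frame(ga), as.data.frame(gb))
})
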