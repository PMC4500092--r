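# Independent oracles used across the suite.  These deliberately avoid the
# package's model-fitting path: effects are computed from raw cell means,
# connectivity by a hand-rolled breadth-first search.

# mean-relative contrasts straight from landscape cell means
oracle_grand_mean <- function(ls) mean(ls$mean_dG)

oracle_state_effect <- function(ls, site, nuc) {
  s <- substr(ls$re, site - 2, site - 2)   # site 3 -> char 1, site 4 -> char 2
  mean(ls$mean_dG[s == nuc]) - mean(ls$mean_dG)
}

oracle_pair_contrast <- function(ls, s3, s4) {
  c3 <- substr(ls$re, 1, 1)
  c4 <- substr(ls$re, 2, 2)
  mean(ls$mean_dG[c3 == s3 & c4 == s4]) - mean(ls$mean_dG) -
    oracle_state_effect(ls, 3, s3) - oracle_state_effect(ls, 4, s4)
}

oracle_sub_effect <- function(ls, site) {
  pg <- enumerate_protein_genotypes()
  der <- pg[[site]][match(ls$protein, pg$label)]
  mean(ls$mean_dG[der]) - mean(ls$mean_dG[!der])
}

oracle_protein_pair <- function(ls, site_i, site_j) {
  pg <- enumerate_protein_genotypes()
  di <- pg[[site_i]][match(ls$protein, pg$label)]
  dj <- pg[[site_j]][match(ls$protein, pg$label)]
  eff_in_derived <- mean(ls$mean_dG[di & dj]) - mean(ls$mean_dG[!di & dj])
  avg_eff <- mean(ls$mean_dG[di]) - mean(ls$mean_dG[!di])
  eff_in_derived - avg_eff
}

# naive breadth-first search over the 128-complex space
oracle_bfs <- function(functional_labels, source, targets) {
  if (!source %in% functional_labels) stop("source not functional")
  jg <- enumerate_joint_genotypes()
  adj <- list()
  for (lab in functional_labels) {
    row <- jg[jg$label == lab, ]
    nb <- joint_neighbors(row$protein, row$re)
    adj[[lab]] <- intersect(nb$label, functional_labels)
  }
  dist <- stats::setNames(rep(Inf, length(functional_labels)), functional_labels)
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nxt in adj[[cur]]) {
      if (is.infinite(dist[nxt])) {
        dist[nxt] <- dist[cur] + 1
        queue <- c(queue, nxt)
      }
    }
  }
  reach <- intersect(targets, functional_labels)
  reach <- reach[is.finite(dist[reach])]
  list(connected = length(reach) > 0 || source %in% targets,
       shortest = if (source %in% targets) 0L
                  else if (length(reach)) as.integer(min(dist[reach]))
                  else NA_integer_)
}

# random complete landscape of iid cell means (for graph/path properties)
random_mean_landscape <- function(seed, sd = 1.5, mean = 10) {
  set.seed(seed)
  jg <- enumerate_joint_genotypes()
  data.frame(protein = jg$protein, re = jg$re,
             mean_dG = stats::rnorm(nrow(jg), mean, sd),
             stringsAsFactors = FALSE)
}

expect_close <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(actual - expected)), tol)
}
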