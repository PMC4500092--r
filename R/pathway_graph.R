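# Functional-complex classification, the neutral network over the joint
# TF-RE sequence space, accessible trajectories, and permissive/restrictive
# gating across the molecular interface.

#' Functional-complex criteria
#'
#' A complex is functional iff (1) its mean dG is strictly greater than the
#' grand mean over all complexes in the landscape, and (2) its affinity
#' constant is within a factor of `fold` of that protein's best target,
#' i.e. `dG >= best_dG(protein) - R T ln(fold)` (1.364 kcal/mol for a
#' tenfold factor at 298.15 K).  Thresholds are always recomputed from the
#' supplied landscape.
#'
#' @param fold fold factor on the affinity constant (default 10; must be > 1).
#' @param temperature_K absolute temperature.
#' @return list of class `functional_criteria`.
#' @export
functional_criteria <- function(fold = 10, temperature_K = 298.15) {
  if (fold <= 1) stop("fold factor must be > 1", call. = FALSE)
  structure(list(fold = fold, temperature_K = temperature_K,
                 dG_window = R_KCAL * temperature_K * log(fold)),
            class = "functional_criteria")
}

.as_landscape <- function(landscape) {
  if (inherits(landscape, "synthetic_landscape")) landscape <- landscape$landscape
  ycol <- .response_column(landscape)
  out <- data.frame(protein = landscape$protein, re = landscape$re,
                    mean_dG = landscape[[ycol]], stringsAsFactors = FALSE)
  jg <- enumerate_joint_genotypes()
  missing <- setdiff(jg$label, joint_label(out$protein, out$re))
  if (length(missing)) {
    stop("incomplete landscape; missing cells: ",
         paste(utils::head(missing, 8), collapse = ", "),
         if (length(missing) > 8) sprintf(" (and %d more)", length(missing) - 8),
         call. = FALSE)
  }
  out <- out[match(jg$label, joint_label(out$protein, out$re)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify every complex in a landscape as functional or not
#'
#' Applies the two-part occupancy criterion of [functional_criteria()] to a
#' complete 8 x 16 landscape of replicate-mean binding energies.
#'
#' @param landscape data.frame (protein, re, mean_dG) covering all 128
#'   complexes, or a `synthetic_landscape`.
#' @param criteria a [functional_criteria()].
#' @return data.frame of class `functional_calls` with columns `protein`,
#'   `re`, `mean_dG`, `functional`, `below_mean`, `outside_fold`,
#'   `is_best_target`; attributes `grand_mean`, `best` (per-protein best
#'   dG, ties all retained) and `criteria`.
#' @export
classify_functional <- function(landscape, criteria = functional_criteria()) {
  stopifnot(inherits(criteria, "functional_criteria"))
  ls <- .as_landscape(landscape)
  grand_mean <- mean(ls$mean_dG)
  best <- tapply(ls$mean_dG, ls$protein, max)
  cutoff <- best[ls$protein] - criteria$dG_window
  ls$below_mean <- !(ls$mean_dG > grand_mean)
  ls$outside_fold <- !(ls$mean_dG >= cutoff)
  ls$functional <- !ls$below_mean & !ls$outside_fold
  ls$is_best_target <- ls$mean_dG == best[ls$protein]
  attr(ls, "grand_mean") <- grand_mean
  attr(ls, "best") <- best
  attr(ls, "criteria") <- criteria
  class(ls) <- c("functional_calls", "data.frame")
  ls
}

.as_calls <- function(x, criteria = functional_criteria()) {
  if (inherits(x, "functional_calls")) x else classify_functional(x, criteria)
}

.functional_set <- function(calls) {
  joint_label(calls$protein[calls$functional], calls$re[calls$functional])
}

#' Build the neutral network of functional complexes
#'
#' Nodes are functional complexes; undirected edges connect functional
#' complexes differing by a single amino acid replacement (`move_type =
#' "protein"`) or a single nucleotide substitution (`move_type = "re"`).
#'
#' @param calls a `functional_calls` data.frame (or a landscape, which is
#'   classified with default criteria first).
#' @return an [igraph::graph] with vertex attribute `name` (joint labels)
#'   and edge attributes `move_type`, `site`.
#' @export
build_joint_graph <- function(calls) {
  calls <- .as_calls(calls)
  fun <- .functional_set(calls)
  if (length(fun) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  rows <- list()
  fun_idx <- stats::setNames(seq_along(fun), fun)
  fc <- calls[calls$functional, , drop = FALSE]
  for (i in seq_len(nrow(fc))) {
    nb <- joint_neighbors(fc$protein[i], fc$re[i])
    here <- joint_label(fc$protein[i], fc$re[i])
    keep <- nb$label %in% fun & nb$label > here   # each undirected edge once
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        from = here, to = nb$label[keep],
        move_type = nb$molecule[keep], site = nb$site[keep],
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(), to = character(),
               move_type = character(), site = character())
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = fun))
}

.ordering_proteins <- function(ordering) {
  # ordering: character vector of the three sites in replacement order;
  # returns the 4 protein labels along that trajectory
  derived <- stats::setNames(logical(3), PROTEIN_SITES)
  labs <- .protein_label(derived)
  for (s in ordering) {
    derived[s] <- TRUE
    labs <- c(labs, .protein_label(derived))
  }
  labs
}

#' Accessibility of the six protein-replacement orderings
#'
#' Evaluates all 3! orderings of the three replacements from the
#' all-ancestral to the all-derived protein.  An ordering is accessible iff
#' every protein along it (endpoints included) has at least one functional
#' RE under the supplied criteria, modelling purifying selection that
#' forbids nonfunctional intermediates.
#'
#' @inheritParams classify_functional
#' @return list of class `path_report` with `scenario = "protein_trajectories"`,
#'   `orderings` (data.frame: ordering, accessible, n_functional per step)
#'   and `functional_res` (per-protein functional RE sets).
#' @export
protein_trajectories <- function(landscape, criteria = functional_criteria()) {
  calls <- .as_calls(landscape, criteria)
  fun_res <- lapply(split(calls$re[calls$functional],
                          factor(calls$protein[calls$functional],
                                 levels = enumerate_protein_genotypes()$label)),
                    as.character)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  rows <- lapply(perms, function(p) {
    ordering <- PROTEIN_SITES[p]
    labs <- .ordering_proteins(ordering)
    counts <- vapply(labs, function(l) length(fun_res[[l]]), 0L)
    data.frame(ordering = paste(ordering, collapse = " -> "),
               accessible = all(counts > 0L),
               step_functional = paste(counts, collapse = ","),
               stringsAsFactors = FALSE)
  })
  structure(list(
    scenario = "protein_trajectories",
    orderings = do.call(rbind, rows),
    n_accessible = sum(vapply(rows, function(r) r$accessible, TRUE)),
    functional_res = fun_res,
    criteria = attr(calls, "criteria")
  ), class = "path_report")
}

#' @export
print.path_report <- function(x, ...) {
  cat("path_report:", x$scenario, "\n")
  if (x$scenario == "protein_trajectories") {
    cat(sprintf("  %d of 6 orderings accessible\n", x$n_accessible))
    print(x$orderings, row.names = FALSE)
  } else {
    cat(sprintf("  source %s -> targets: %s\n", x$source,
                paste(x$targets, collapse = ", ")))
    cat(sprintf("  connected: %s; shortest path length: %s; %d shortest path(s) enumerated\n",
                x$connected, format(x$shortest_length), length(x$paths)))
  }
  invisible(x)
}

#' Neutral paths between complexes in the joint sequence space
#'
#' Breadth-first connectivity from a functional source complex to a set of
#' target complexes along the neutral network; every step changes exactly
#' one molecule and visits only functional complexes.  Shortest paths to
#' the nearest reachable target are enumerated up to `cap`.
#'
#' @param graph a [build_joint_graph()] result (or `functional_calls`, from
#'   which the graph is built).
#' @param source,targets joint labels ("protein:RE").
#' @param cap maximum number of shortest paths to enumerate.
#' @return list of class `path_report` with `connected`,
#'   `shortest_length`, `paths` (each a character vector of joint labels)
#'   and `reachable_targets`.
#' @export
joint_paths <- function(graph, source, targets, cap = 10000) {
  if (!igraph::is_igraph(graph)) graph <- build_joint_graph(graph)
  nodes <- igraph::V(graph)$name
  if (!source %in% nodes) {
    stop("source complex ", source, " is not functional", call. = FALSE)
  }
  targets <- unique(targets)
  if (source %in% targets) {
    return(structure(list(scenario = "joint_paths", source = source,
                          targets = targets, connected = TRUE,
                          shortest_length = 0L, paths = list(source),
                          reachable_targets = source), class = "path_report"))
  }
  present <- intersect(targets, nodes)
  if (length(present) == 0L) {
    return(structure(list(scenario = "joint_paths", source = source,
                          targets = targets, connected = FALSE,
                          shortest_length = NA_integer_, paths = list(),
                          reachable_targets = character()),
                     class = "path_report"))
  }
  dm <- igraph::distances(graph, v = source, to = present)
  d <- stats::setNames(dm[1, ], colnames(dm))
  reachable <- present[is.finite(d)]
  if (length(reachable) == 0L) {
    return(structure(list(scenario = "joint_paths", source = source,
                          targets = targets, connected = FALSE,
                          shortest_length = NA_integer_, paths = list(),
                          reachable_targets = character()),
                     class = "path_report"))
  }
  dmin <- min(d[is.finite(d)])
  nearest <- reachable[d[reachable] == dmin]
  paths <- list()
  for (tg in nearest) {
    sp <- igraph::all_shortest_paths(graph, from = source, to = tg)$vpaths
    for (p in sp) {
      if (length(paths) >= cap) break
      paths[[length(paths) + 1L]] <- igraph::V(graph)$name[p]
    }
    if (length(paths) >= cap) break
  }
  structure(list(scenario = "joint_paths", source = source, targets = targets,
                 connected = TRUE, shortest_length = as.integer(dmin),
                 paths = paths, reachable_targets = reachable),
            class = "path_report")
}

#' Permissive and restrictive gating across the landscape
#'
#' For each functional complex g, each admissible move m from g (one whose
#' endpoint is functional) and each move m' acting on a different position:
#' m is \emph{permissive} for m' at g if m' is inadmissible from g but
#' admissible from g after m, and \emph{restrictive} if the converse holds.
#' Cross-molecule events (m and m' in different molecules) are flagged;
#' same-molecule gating is reported too but flagged separately.
#'
#' @inheritParams classify_functional
#' @param cross_only if TRUE, report only cross-molecule events.
#' @return data.frame of class `gating_report` with columns `context`
#'   (joint label of g), `gate_molecule`, `gate_site`, `gate_to`,
#'   `focal_molecule`, `focal_site`, `focal_to`, `type`
#'   ("permissive"/"restrictive"), `cross_molecule`.
#' @export
gating_analysis <- function(landscape, criteria = functional_criteria(),
                            cross_only = FALSE) {
  calls <- .as_calls(landscape, criteria)
  fun <- .functional_set(calls)
  is_fun <- stats::setNames(calls$functional,
                            joint_label(calls$protein, calls$re))
  fc <- calls[calls$functional, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(fc))) {
    g_protein <- fc$protein[i]; g_re <- fc$re[i]
    g_label <- joint_label(g_protein, g_re)
    nb <- joint_neighbors(g_protein, g_re)
    nb$admissible <- unname(is_fun[nb$label])
    for (mi in which(nb$admissible)) {
      m <- nb[mi, ]
      nb2 <- joint_neighbors(m$protein, m$re)
      for (fi in seq_len(nrow(nb))) {
        mp <- nb[fi, ]
        if (mp$molecule == m$molecule && mp$site == m$site) next
        # m' after m: same (molecule, site, to) move applied to g*m
        j <- which(nb2$molecule == mp$molecule & nb2$site == mp$site &
                   nb2$to == mp$to)
        ok_before <- mp$admissible
        ok_after <- unname(is_fun[nb2$label[j]])
        type <- if (!ok_before && ok_after) "permissive"
                else if (ok_before && !ok_after) "restrictive"
                else NA_character_
        if (is.na(type)) next
        cross <- m$molecule != mp$molecule
        if (cross_only && !cross) next
        rows[[length(rows) + 1L]] <- data.frame(
          context = g_label,
          gate_molecule = m$molecule, gate_site = m$site, gate_to = m$to,
          focal_molecule = mp$molecule, focal_site = mp$site, focal_to = mp$to,
          type = type, cross_molecule = cross, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    context = character(), gate_molecule = character(), gate_site = character(),
    gate_to = character(), focal_molecule = character(), focal_site = character(),
    focal_to = character(), type = character(), cross_molecule = logical(),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gating_report", "data.frame")
  out
}
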