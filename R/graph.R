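#' Act prevalence across trials
#'
#' For each code, the percentage of trials in which the act occurs at least
#' once (the per-node percentage shown beneath act names in kinematic
#' diagrams).
#'
#' @param trials list of trials.
#' @param acts optional codes to report on; acts never observed get 0.
#'   Defaults to the codes observed in `trials`.
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @export
act_prevalence <- function(trials, acts = NULL) {
  trials <- check_trials(trials)
  all_codes <- unlist(lapply(trials, function(tr) unique(tr$acts$code)))
  counts <- table(factor(all_codes, levels = acts %||% unique(all_codes)))
  out <- 100 * counts / length(trials)
  stats::setNames(as.numeric(out), names(out))
}

#' Ethogram graph styling
#'
#' Visual conventions of the kinematic diagrams: phase colors (premating
#' blue, mating red, postmating gray), the pen-width range edges are scaled
#' into, the border-width range for nodes, and the edge label format.
#'
#' @param phase_colors named character vector mapping phase to color.
#' @param pen_width length-2 numeric `c(min, max)` for edge pen widths;
#'   transition percentages are mapped affinely onto this range.
#' @param node_pen_width length-2 numeric range for node border widths,
#'   scaled from act prevalence.
#' @param edge_label_digits decimals on edge percentage labels.
#' @return A list of class `ethochain_style`.
#' @export
graph_style <- function(phase_colors = c(premating = "blue", mating = "red",
                                         postmating = "gray"),
                        pen_width = c(0.5, 6.0),
                        node_pen_width = c(1.0, 4.0),
                        edge_label_digits = 1) {
  stopifnot(length(pen_width) == 2L, all(pen_width > 0), pen_width[1] < pen_width[2],
            length(node_pen_width) == 2L, all(node_pen_width > 0),
            node_pen_width[1] < node_pen_width[2])
  structure(list(phase_colors = phase_colors, pen_width = pen_width,
                 node_pen_width = node_pen_width,
                 edge_label_digits = edge_label_digits),
            class = "ethochain_style")
}

#' Build an ethogram graph of significant transitions
#'
#' Nodes are the acts appearing in at least one significant transition;
#' edges are the significant cells with their transition percentages. Node
#' phases come from the repertoire defaults (an act occurring in several
#' phases keeps its repertoire phase). Works on an [analyze()] result or on
#' a packaged reference table.
#'
#' @param x an `ethochain_analysis` or `ethochain_fixture`.
#' @param prevalence optional named vector from [act_prevalence()]; shown
#'   beneath node labels and used for node border widths.
#' @param repertoire an `ethochain_repertoire` supplying node phases.
#' @param ... unused.
#' @return An object of class `ethochain_graph`: list with `nodes`
#'   (data.frame code/phase/prevalence) and `edges` (data.frame
#'   from/to/t_pct), both sorted lexicographically for deterministic output.
#' @examples
#' fx <- load_reference_table("mated_female")
#' g <- build_graph(fx, repertoire = reference_repertoire("female"))
#' nrow(g$nodes)  # 8
#' nrow(g$edges)  # 9
#' @export
build_graph <- function(x, prevalence = NULL, repertoire = NULL, ...) {
  UseMethod("build_graph")
}

new_ethogram_graph <- function(edges, prevalence, repertoire) {
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  codes <- sort(unique(c(edges$from, edges$to)))
  phase <- rep(NA_character_, length(codes))
  if (!is.null(repertoire)) {
    phase <- repertoire$acts$phase[match(codes, repertoire$acts$code)]
  }
  prev <- rep(NA_real_, length(codes))
  if (!is.null(prevalence)) prev <- unname(prevalence[codes])
  nodes <- data.frame(code = codes, phase = phase, prevalence = prev)
  if (nrow(edges) == 0L) warning("no significant transitions: empty graph", call. = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "ethochain_graph")
}

#' @rdname build_graph
#' @export
build_graph.ethochain_analysis <- function(x, prevalence = NULL, repertoire = NULL, ...) {
  sig <- x$cells[x$cells$significant, , drop = FALSE]
  edges <- data.frame(from = sig$antecedent, to = sig$subsequent, t_pct = sig$t_pct)
  new_ethogram_graph(edges, prevalence, repertoire)
}

#' @rdname build_graph
#' @export
build_graph.ethochain_fixture <- function(x, prevalence = NULL, repertoire = NULL, ...) {
  sig <- x$cells[x$cells$significant, , drop = FALSE]
  edges <- data.frame(from = sig$antecedent, to = sig$subsequent, t_pct = sig$t_pct)
  new_ethogram_graph(edges, prevalence, repertoire)
}

#' @export
print.ethochain_graph <- function(x, ...) {
  cat(sprintf("<ethogram graph: %d nodes, %d edges>\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Affine map of values onto [lo, hi]; constant input maps to the midpoint.
scale_into <- function(values, range) {
  if (length(values) == 0L) return(numeric(0))
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) return(rep(mean(range), length(values)))
  range[1] + (values - lo) / (hi - lo) * (range[2] - range[1])
}

#' Render an ethogram graph as DOT text
#'
#' Emits a deterministic DOT (Graphviz) directed-graph document: nodes are
#' circles colored by phase with border width scaled from prevalence and
#' the prevalence percentage beneath the act code; edge pen width is
#' affinely scaled from the transition percentage into the style's range
#' (strictly monotone: higher percentage, thicker line; equal percentages,
#' equal width) and the percentage is the edge label. Rendering to an image
#' is left to any external `dot` binary.
#'
#' @param graph an `ethochain_graph`.
#' @param style an [graph_style()].
#' @param path optional file to write the DOT text to.
#' @return The DOT document as a single character string (invisibly when
#'   `path` is given).
#' @export
to_dot <- function(graph, style = graph_style(), path = NULL) {
  nodes <- graph$nodes
  edges <- graph$edges
  known <- c(names(style$phase_colors), NA)
  bad <- nodes$code[!nodes$phase %in% known]
  if (length(bad) > 0L) {
    abort(sprintf("unknown phase for node(s): %s", paste(bad, collapse = ", ")), "style_error")
  }
  node_pen <- rep(mean(style$node_pen_width), nrow(nodes))
  has_prev <- !is.na(nodes$prevalence)
  if (any(has_prev)) {
    node_pen[has_prev] <- scale_into(nodes$prevalence[has_prev], style$node_pen_width)
  }
  node_lines <- vapply(seq_len(nrow(nodes)), function(i) {
    label <- if (has_prev[i]) {
      sprintf("%s\\n%.1f%%", nodes$code[i], nodes$prevalence[i])
    } else nodes$code[i]
    color <- if (is.na(nodes$phase[i])) "black" else style$phase_colors[[nodes$phase[i]]]
    sprintf("  \"%s\" [label=\"%s\", shape=circle, color=%s, penwidth=%.2f];",
            nodes$code[i], label, color, node_pen[i])
  }, character(1))
  pen <- scale_into(edges$t_pct, style$pen_width)
  edge_lines <- vapply(seq_len(nrow(edges)), function(i) {
    sprintf("  \"%s\" -> \"%s\" [label=\"%.*f\", penwidth=%.3f];",
            edges$from[i], edges$to[i], style$edge_label_digits, edges$t_pct[i], pen[i])
  }, character(1))
  dot <- paste(c("digraph ethogram {", "  rankdir=TB;", node_lines, edge_lines, "}"),
               collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}

#' Parse DOT text emitted by [to_dot()]
#'
#' Minimal parser for the package's own DOT subset, recovering node codes
#' and directed edges; supports round-trip checks of emitted graphs.
#'
#' @param dot DOT document as a character string (or lines).
#' @return List with `nodes` (character vector) and `edges` (data.frame
#'   from/to).
#' @export
parse_dot <- function(dot) {
  lines <- unlist(strsplit(paste(dot, collapse = "\n"), "\n", fixed = TRUE))
  edge_re <- '^\\s*"([^"]+)"\\s*->\\s*"([^"]+)"'
  node_re <- '^\\s*"([^"]+)"\\s*\\['
  is_edge <- grepl(edge_re, lines)
  is_node <- grepl(node_re, lines) & !is_edge
  edges <- data.frame(
    from = sub(paste0(edge_re, ".*$"), "\\1", lines[is_edge]),
    to = sub(paste0(edge_re, ".*$"), "\\2", lines[is_edge])
  )
  list(nodes = sub(paste0(node_re, ".*$"), "\\1", lines[is_node]), edges = edges)
}
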