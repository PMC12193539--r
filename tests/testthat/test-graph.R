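test_that("act prevalence is the per-trial occurrence percentage", {
  trs <- c(
    lapply(1:9, function(i) trial(paste0("t", i), c("MW", "MHFAR"))),
    lapply(10:26, function(i) trial(paste0("t", i), c("MHFAR", "MEE")))
  )
  prev <- act_prevalence(trs, acts = c("MW", "MHFAR", "MEE", "MQP"))
  expect_equal(unname(prev["MHFAR"]), 100)            # all trials
  expect_equal(unname(prev["MW"]), 100 * 9 / 26)      # 34.6
  expect_equal(unname(prev["MQP"]), 0)                # absent act
})

test_that("ethogram graphs have the published node and edge counts", {
  rep_f <- reference_repertoire("female")
  g <- build_graph(load_reference_table("mated_female"), repertoire = rep_f)
  expect_equal(nrow(g$nodes), 8)
  expect_equal(nrow(g$edges), 9)

  g_vm <- build_graph(load_reference_table("virgin_male"),
                      repertoire = reference_repertoire("male"))
  expect_equal(nrow(g_vm$nodes), 11)
  # only significant cells become edges: the inferred virgin_female cell is excluded
  g_vf <- build_graph(load_reference_table("virgin_female"),
                      repertoire = rep_f)
  expect_equal(nrow(g_vf$edges),
               sum(load_reference_table("virgin_female")$cells$significant))
})

test_that("DOT output is structurally valid, styled and deterministic", {
  fx <- load_reference_table("mated_female")
  g <- build_graph(fx, repertoire = reference_repertoire("female"))
  dot <- to_dot(g)
  expect_match(dot, "^digraph")
  expect_equal(length(gregexpr("->", dot, fixed = TRUE)[[1]]), nrow(g$edges))
  expect_identical(to_dot(g), dot)  # byte-identical across runs
  expect_match(dot, "color=red")    # mating phase styling present
  expect_match(dot, "color=blue")
  expect_match(dot, "color=gray")
})

test_that("edge pen width is strictly monotone in the transition percentage", {
  edges <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "A"),
                      t_pct = c(7.75, 3.48, 3.48))
  g <- structure(list(nodes = data.frame(code = c("A", "B", "C"),
                                         phase = "premating", prevalence = NA_real_),
                      edges = edges), class = "ethochain_graph")
  dot <- to_dot(g)
  widths <- as.numeric(sub(".*penwidth=([0-9.]+)\\].*", "\\1",
                           grep("->", strsplit(dot, "\n")[[1]], value = TRUE)))
  by_edge <- data.frame(t = edges$t_pct[order(edges$from, edges$to)], w = widths)
  expect_gt(by_edge$w[by_edge$t == 7.75][1], max(by_edge$w[by_edge$t == 3.48]))
  expect_equal(by_edge$w[by_edge$t == 3.48][1], by_edge$w[by_edge$t == 3.48][2])
})

test_that("parsing emitted DOT recovers the graph exactly", {
  for (grp in reference_groups()) {
    rep_ <- reference_repertoire(load_reference_table(grp)$sex)
    g <- build_graph(load_reference_table(grp), repertoire = rep_)
    parsed <- parse_dot(to_dot(g))
    expect_equal(parsed$nodes, g$nodes$code)
    expect_equal(parsed$edges$from, g$edges$from)
    expect_equal(parsed$edges$to, g$edges$to)
  }
})

test_that("degenerate graphs are handled explicitly", {
  empty <- expect_warning(
    new_graph <- build_graph(
      structure(list(cells = data.frame(antecedent = character(), subsequent = character(),
                                        t_pct = numeric(), significant = logical())),
                class = "ethochain_analysis")),
    "empty"
  )
  dot <- to_dot(new_graph)
  expect_match(dot, "^digraph")
  expect_false(grepl("->", dot, fixed = TRUE))

  bad <- structure(list(nodes = data.frame(code = "A", phase = "courtship",
                                           prevalence = NA_real_),
                        edges = data.frame(from = character(), to = character(),
                                           t_pct = numeric())),
                   class = "ethochain_graph")
  expect_error(to_dot(bad), "A", class = "style_error")
})
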