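make_edges <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(drug = r[[1]], target = r[[2]], sign = as.integer(r[[3]]),
               pharmacological = as.logical(r[[4]]), stringsAsFactors = FALSE)
  }))
}

test_that("constructor validates bipartiteness and uniqueness", {
  expect_error(signed_dtn(make_edges(list("x", "x", 1, FALSE))),
               "both drug and target")
  expect_error(signed_dtn(rbind(make_edges(list("d", "t", 1, FALSE)),
                                make_edges(list("d", "t", -1, FALSE)))),
               "duplicate")
  expect_error(signed_dtn(make_edges(list("d", "t", 2, FALSE))), "signs")
})

test_that("restrict_to_signed keeps exactly the signed edges, drops isolates", {
  net <- signed_dtn(make_edges(
    list("d1", "t1", 1, FALSE), list("d1", "t2", -1, FALSE),
    list("d2", "t3", 0, FALSE)
  ))
  s <- restrict_to_signed(net)
  expect_equal(nrow(s$edges), 2)
  expect_false("d2" %in% s$drugs)
  expect_false("t3" %in% s$targets)
  expect_equal(summarize_network(s)$n_unsigned, 0)

  all_unsigned <- signed_dtn(make_edges(list("d1", "t1", 0, FALSE)))
  expect_equal(nrow(restrict_to_signed(all_unsigned)$edges), 0)
})

test_that("restrict_to_pharmacological keeps flagged edges only", {
  net <- signed_dtn(make_edges(
    list("d1", "t1", 1, TRUE), list("d1", "t2", -1, FALSE),
    list("d2", "t2", 1, FALSE), list("d2", "t3", -1, FALSE)
  ))
  p <- restrict_to_pharmacological(net)
  expect_equal(nrow(p$edges), 1)
  expect_equal(p$edges$target, "t1")

  all_pharm <- signed_dtn(make_edges(list("d1", "t1", 1, TRUE),
                                     list("d2", "t1", -1, TRUE)))
  expect_equal(nrow(restrict_to_pharmacological(all_pharm)$edges), 2)
})

test_that("summaries count what a direct recount counts", {
  net <- signed_dtn(make_edges(
    list("d1", "t1", 1, TRUE), list("d1", "t2", -1, FALSE),
    list("d2", "t1", -1, FALSE), list("d2", "t3", 0, TRUE)
  ))
  s <- summarize_network(net)
  expect_equal(s$n_positive, 1)
  expect_equal(s$n_negative, 2)
  expect_equal(s$n_unsigned, 1)
  expect_equal(s$n_positive + s$n_negative + s$n_unsigned, s$n_edges)
  expect_equal(s$n_pharmacological, 2)

  empty <- signed_dtn(make_edges(list("d", "t", 1, FALSE))[0, ])
  se <- summarize_network(empty)
  expect_true(all(unlist(se) == 0))
})

test_that("degree profiles split totals into sign counts", {
  star <- signed_dtn(make_edges(
    list("D", "t1", 1, FALSE), list("D", "t2", 1, FALSE),
    list("D", "t3", 1, FALSE)
  ))
  prof <- degree_profiles(star)
  d_row <- prof[prof$node_id == "D", ]
  expect_equal(d_row$n_total, 3)
  expect_equal(d_row$n_positive, 3)
  expect_equal(d_row$n_negative, 0)

  mixed <- signed_dtn(make_edges(
    list("d1", "t1", 1, FALSE), list("d1", "t2", -1, FALSE),
    list("d1", "t3", 0, FALSE)
  ))
  r <- degree_profiles(mixed)
  r <- r[r$node_id == "d1", ]
  expect_equal(r$n_total, 3)
  expect_equal(r$n_positive + r$n_negative, 2)  # one unsigned

  empty <- signed_dtn(make_edges(list("d", "t", 1, FALSE))[0, ])
  expect_equal(nrow(degree_profiles(empty)), 0)
})

test_that("connected components partition the graph, sorted by size", {
  two_stars <- signed_dtn(make_edges(
    list("d1", "t1", 1, FALSE), list("d1", "t2", 1, FALSE),
    list("d2", "t3", -1, FALSE)
  ))
  comps <- connected_components(two_stars)
  expect_equal(nrow(comps), 2)
  expect_equal(comps$n_nodes, c(3, 2))
  expect_equal(sum(comps$n_drugs), 2)
  expect_equal(sum(comps$n_targets), 3)

  single <- signed_dtn(make_edges(list("d", "t", 1, FALSE)))
  c1 <- connected_components(single)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$drug_fraction, 1.0)
  expect_equal(c1$target_fraction, 1.0)

  square <- generate_fixture("fig3_cycles")
  sub <- signed_dtn(square$edges[square$edges$drug %in% c("cohD1", "cohD2"), ])
  expect_equal(nrow(connected_components(sub)), 1)
})

test_that("edge list loading collapses multi-action rows per the rules", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "drug_id\ttarget_id\taction\tpharmacological",
    "D1\tT1\tagonist\tyes",
    "D1\tT1\tactivator\tno",
    "D2\tT1\tagonist\tno",
    "D2\tT2\tantagonist\tunknown",
    "D3\tT2\tagonist\tno",
    "D3\tT2\tantagonist\tno"
  ), path)
  net <- load_edge_list(path)
  expect_equal(nrow(net$edges), 4)
  rep <- attr(net, "load_report")
  expect_equal(rep$rows_read, 6)
  expect_equal(rep$rows_collapsed, 2)

  e11 <- net$edges[net$edges$drug == "D1" & net$edges$target == "T1", ]
  expect_equal(e11$sign, 1L)            # agreeing labels keep their sign
  expect_true(e11$pharmacological)      # OR of the rows
  e32 <- net$edges[net$edges$drug == "D3" & net$edges$target == "T2", ]
  expect_equal(e32$sign, 0L)            # conflicting signs collapse to 0
  expect_true(e32$conflicting)
  e22 <- net$edges[net$edges$drug == "D2" & net$edges$target == "T2", ]
  expect_false(e22$pharmacological)     # unknown treated as no
})

test_that("edge list loading errors name structural problems", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("drug_id\ttarget_id\taction", p1)
  expect_error(load_edge_list(p1), "pharmacological")

  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("drug_id\ttarget_id\taction\tpharmacological", p2)
  expect_error(load_edge_list(p2), "empty")

  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_id\ttarget_id\taction\tpharmacological",
               "A\tB\tagonist\tno",
               "B\tC\tagonist\tno"), p3)
  expect_error(load_edge_list(p3), "both drug and target")
})

test_that("unknown action labels load with a warning and sign 0", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_id\ttarget_id\taction\tpharmacological",
               "D1\tT1\tmystery-action\tno"), path)
  expect_warning(net <- load_edge_list(path), "mystery-action")
  expect_equal(net$edges$sign, 0L)
  expect_equal(attr(net, "load_report")$unknown_labels, "mystery-action")
})

test_that("write/load round trip reproduces the network exactly", {
  set.seed(42)
  net <- random_test_network(12, 8, 30, unsigned_prob = 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  net2 <- load_edge_list(path)
  expect_equal(net2$drugs, net$drugs)
  expect_equal(net2$targets, net$targets)
  ord <- function(e) e[order(e$drug, e$target),
                       c("drug", "target", "sign", "pharmacological")]
  expect_equal(ord(net2$edges), ord(net$edges), ignore_attr = TRUE)
})

test_that("conflicting edges survive the edge-list round trip", {
  e <- data.frame(drug = "d1", target = "t1", sign = 0L,
                  pharmacological = TRUE, conflicting = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(signed_dtn(e), path)
  net2 <- load_edge_list(path)
  expect_equal(net2$edges$sign, 0L)
  expect_true(net2$edges$conflicting)
  expect_true(net2$edges$pharmacological)
})
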