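test_that("density matches the directed-symmetric convention", {
  expect_equal(round_half_up(net_density(fix_network(11, all_pairs(11)[1:42, ])), 2),
               0.76)
  expect_equal(net_density(fix_complete(11)), 1)
  expect_equal(net_density(fix_network(11, NULL)), 0)
  expect_error(net_density(fix_network(1, NULL)), "at least 2")
})

test_that("degree centrality counts distinct tied actors", {
  star <- fix_star(5)
  expect_equal(actor_degree(star, "v1"), 4L)
  expect_equal(actor_degree(star, "v2"), 1L)
  expect_equal(actor_degree(fix_network(4, NULL), "v3"), 0L)
  expect_equal(actor_degree(fix_complete(11), "v1"), 10L)
  expect_error(actor_degree(star, "nobody"), "unknown actor")

  expect_equal(unname(degree_vector(fix_path(4))), c(1L, 2L, 2L, 1L))
})

test_that("average degree is directed ties over actors", {
  expect_equal(round_half_up(average_degree(fix_network(11, all_pairs(11)[1:42, ])), 2),
               7.64)
  expect_equal(average_degree(fix_complete(11)), 10)
  expect_equal(average_degree(fix_network(5, NULL)), 0)
})

test_that("betweenness closed forms hold", {
  expect_equal(unname(betweenness_raw(fix_complete(6))), rep(0, 6))
  expect_equal(unname(betweenness_raw(fix_path(3))), c(0, 1, 0))
  # star centre carries every one of the (n-1)(n-2)/2 pairs
  expect_equal(unname(betweenness_raw(fix_star(11))[1]), 45)
  expect_equal(unname(betweenness_normalized(fix_star(11))[1]), 100)
  expect_equal(unname(betweenness_normalized(fix_path(3))[2]), 100)
  expect_equal(unname(betweenness_normalized(fix_complete(11))),
               rep(0, 11))
  expect_error(betweenness_normalized(fix_network(2, NULL)),
               "at least 3")
})

test_that("Brandes equals the geodesic-counting oracle and igraph", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    e <- random_edges(n, stats::runif(1, 0.2, 0.8))
    nw <- fix_network(n, e)
    got <- unname(betweenness_raw(nw))
    expect_equal(got, oracle_betweenness(edges_to_adjacency(n, e)))
    g <- igraph::graph_from_adjacency_matrix(
      edges_to_adjacency(n, e), mode = "undirected")
    expect_equal(got, unname(igraph::betweenness(g)), tolerance = 1e-10)
  }
})

test_that("degree centralization matches Freeman's formula", {
  expect_equal(degree_centralization(fix_star(11)), 100)
  expect_equal(degree_centralization(fix_complete(8)), 0)
  # n = 4 path: degrees 1,2,2,1 -> 100 * 2 / 6
  expect_equal(degree_centralization(fix_path(4)), 100 * 2 / 6)
  expect_error(degree_centralization(fix_network(2, NULL)), "at least 3")
})

test_that("group E-I index counts internal and external ties", {
  # 5 actors, group = {v1, v2} (Hausa); ties: v1-v2 internal,
  # v1-v3, v1-v4, v2-v5 external -> E = 3, I = 1, EI = 0.5
  nw <- fix_network(5, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 5)),
                    actor_overrides = list(
                      ethnicity = c("Hausa", "Hausa", "Others",
                                    "Others", "Others")))
  res <- group_ei_index(nw, "ethnicity", "Hausa")
  expect_equal(res$external, 3)
  expect_equal(res$internal, 1)
  expect_equal(res$ei_index, 0.5)

  # all-external ties -> +1; all-internal -> -1
  bip <- fix_network(4, rbind(c(1, 3), c(2, 4)),
                     actor_overrides = list(
                       ethnicity = c("Hausa", "Hausa", "Others",
                                     "Others")))
  expect_equal(group_ei_index(bip, "ethnicity", "Hausa")$ei_index, 1)
  intern <- fix_network(4, rbind(c(1, 2), c(3, 4)),
                        actor_overrides = list(
                          ethnicity = c("Hausa", "Hausa", "Others",
                                        "Others")))
  expect_equal(group_ei_index(intern, "ethnicity", "Hausa")$ei_index, -1)

  # empty group and tieless group are undefined
  allh <- fix_complete(4)
  expect_true(is.na(group_ei_index(allh, "ethnicity", "Others")$ei_index))
  expect_true(is.na(group_ei_index(fix_network(4, NULL), "ethnicity",
                                   "Hausa")$ei_index))

  # ties touching an NA-attribute actor are excluded from both counts
  nw_na <- fix_network(4, rbind(c(1, 2), c(1, 4), c(3, 4)),
                       actor_overrides = list(
                         marital_status = c("married", "married",
                                            "married", "single"),
                         marriage_type = c("monogamy", "polygamy",
                                           "monogamy", NA)))
  res <- group_ei_index(nw_na, "marriage_type", "monogamy")
  expect_equal(res$external, 1)  # only v1-v2 counted
  expect_equal(res$internal, 0)

  expect_error(group_ei_index(allh, "ethnicity", "Klingon"),
               "unknown group")
})

test_that("actor homophily uses the strict-majority rule", {
  # v1 with 7 of 10 ties same-ethnicity -> homophilic
  eth <- c("Hausa", rep("Hausa", 7), rep("Others", 3))
  nw <- fix_network(11, cbind(1L, 2:11),
                    actor_overrides = list(ethnicity = eth))
  expect_true(actor_homophily(nw, "v1", "ethnicity"))

  # exactly half internal -> E - I = 0 -> not homophilic
  half <- fix_network(5, cbind(1L, 2:5),
                      actor_overrides = list(
                        ethnicity = c("Hausa", "Hausa", "Hausa",
                                      "Others", "Others")))
  expect_false(actor_homophily(half, "v1", "ethnicity"))
  # ... but a permissive threshold flips the boundary case
  expect_true(actor_homophily(half, "v1", "ethnicity", threshold = 1))

  # isolated actor undefined
  iso <- fix_network(3, rbind(c(1, 2)))
  expect_true(is.na(actor_homophily(iso, "v3", "ethnicity")))
})

test_that("homophily summaries aggregate on role denominators", {
  expect_equal(
    summarize_homophily_counts("ethnicity", 20, 175)$total_pct, 88.6)
  expect_equal(
    summarize_homophily_counts("cbdic_use", 17, 162)$total_pct, 81.4)
  row <- summarize_homophily_counts("x", 0, 0)
  expect_equal(row$total_count, 0)
  expect_equal(row$total_pct, 0)

  # end-to-end on a collection where every actor is homophilic:
  # complete networks of all-Hausa actors
  coll <- study_collection(list(fix_complete(5, label = "N1"),
                                fix_complete(5, label = "N2")))
  hs <- homophily_summary(coll, "ethnicity")
  expect_equal(hs$ego_count, 2)
  expect_equal(hs$alter_count, 8)
  # denominators are the actual roster sizes (2 egos, 8 alters)
  expect_equal(hs$total_pct, 100)
})

test_that("network_summary emits one consistent metrics row", {
  nw <- fix_network(11, all_pairs(11)[1:42, ], label = "ROW")
  row <- network_summary(nw)
  expect_equal(row$directed_ties, 84L)
  expect_equal(round_half_up(row$density, 2), 0.76)
  expect_equal(round_half_up(row$average_degree, 2), 7.64)
  expect_equal(row$average_degree * row$n_actors, row$directed_ties)
  expect_equal(row$cbdic_users, 11)

  full <- network_summary(fix_complete(11))
  expect_equal(full$density, 1)
  expect_equal(full$ego_nbetweenness, 0)
  expect_equal(full$average_nbetweenness, 0)
  expect_equal(full$degree_centralization, 0)

  tiny <- network_summary(fix_network(2, rbind(c(1, 2))))
  expect_equal(tiny$density, 1)
  expect_true(is.na(tiny$degree_centralization))
  expect_true(is.na(tiny$ego_nbetweenness))
})

test_that("metrics are invariant under actor relabeling", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    e <- random_edges(n, 0.5)
    nw <- fix_network(n, e)
    perm <- sample(n)
    relabeled <- fix_network(n, cbind(match(e[, 1], perm),
                                      match(e[, 2], perm)))
    expect_equal(net_density(relabeled), net_density(nw))
    expect_equal(sort(unname(degree_vector(relabeled))),
                 sort(unname(degree_vector(nw))))
    expect_equal(sort(unname(betweenness_raw(relabeled))),
                 sort(unname(betweenness_raw(nw))))
    expect_equal(degree_centralization(relabeled),
                 degree_centralization(nw))
    # per-actor outputs permute: actor j in nw is actor match(j, perm)
    # in the relabeled network
    br <- betweenness_raw(nw)
    br2 <- betweenness_raw(relabeled)
    expect_equal(unname(br2[match(seq_len(n), perm)]), unname(br))
  }
})
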