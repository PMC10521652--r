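# Contact detection, buried areas, connected-component clusters.

test_that("well-separated residues make no contacts; close ones exactly one", {
  far <- toy_model(c("I", "I"), spacing = 20)
  far <- with_sc(far, 1, c("CG1", "CD1"), rbind(c(0, 1.5, 1), c(0, 2.8, 2)))
  far <- with_sc(far, 2, c("CG1", "CD1"), rbind(c(20, 1.5, 1), c(20, 2.8, 2)))
  expect_equal(nrow(pairwise_contacts(far)), 0L)

  near <- toy_model(c("I", "I"), spacing = 20)  # CB far; sc atoms close
  near <- with_sc(near, 1, c("CG1", "CD1"), rbind(c(8, 0, 1), c(9, 0, 1)))
  near <- with_sc(near, 2, c("CG1", "CD1"), rbind(c(12.9, 0, 1), c(13.9, 0, 1)))
  ct <- pairwise_contacts(near)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$min_dist, 3.9, tolerance = 1e-6)
  expect_gt(ct$area, 0)
})

test_that("poly-Ala has no ILV contacts or clusters", {
  m <- toy_model(rep("A", 10))
  ct <- pairwise_contacts(m)
  expect_equal(nrow(ct), 0L)
  cl <- build_clusters(ct)
  expect_equal(cl$totals$n_clusters, 0L)
  expect_equal(cl$totals$total_contacts, 0L)
  expect_equal(cl$totals$total_area, 0)
})

test_that("contacts are invariant to rigid motion and renumbering", {
  m <- ovoid_model()
  ct <- pairwise_contacts(m, n_points = 480)
  m2 <- transform_model(m, random_rotation(13), c(4, 4, -9))
  ct2 <- pairwise_contacts(m2, n_points = 480)
  # the sphere-point grid is fixed in the laboratory frame, so buried areas
  # carry a small orientation-dependent quadrature error; the contact set is
  # stable up to borderline pairs
  expect_lt(abs(nrow(ct2) - nrow(ct)), 3)
  common <- merge(as.data.frame(ct), as.data.frame(ct2),
                  by = c("res_i", "res_j"))
  expect_gt(nrow(common), 0.98 * nrow(ct))
  expect_lt(max(abs(common$area.x - common$area.y)), 5)
  expect_lt(max(abs(common$min_dist.x - common$min_dist.y)), 1e-6)
  # renumbering shifts labels only
  m3 <- m
  m3$residue <- m3$residue + 100L
  ct3 <- pairwise_contacts(m3, n_points = 480)
  expect_equal(ct3$res_i, ct$res_i + 100L)
  expect_equal(ct3$area, ct$area)
})

test_that("clusters are the connected components (union-find oracle)", {
  union_find <- function(edges, nodes) {
    parent <- stats::setNames(nodes, nodes)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (k in seq_len(nrow(edges))) {
      a <- find(as.character(edges$res_i[k])); b <- find(as.character(edges$res_j[k]))
      if (a != b) parent[[a]] <- b
    }
    vapply(nodes, function(x) find(x), character(1))
  }
  set.seed(31)
  for (trial in 1:5) {
    n <- 30
    ne <- sample(10:40, 1)
    edges <- tibble::tibble(res_i = sample(n, ne, TRUE),
                            res_j = sample(n, ne, TRUE))
    edges <- edges[edges$res_i != edges$res_j, ]
    swap <- edges$res_i > edges$res_j
    tmp <- edges$res_i[swap]; edges$res_i[swap] <- edges$res_j[swap]
    edges$res_j[swap] <- tmp
    edges <- unique(edges)
    edges$min_dist <- 4; edges$area <- 20; edges$n_atom_pairs <- 1L
    cl <- build_clusters(edges)
    nodes <- as.character(sort(unique(c(edges$res_i, edges$res_j))))
    oracle <- union_find(edges, nodes)
    # same partition: identical co-membership
    got <- stats::setNames(cl$members$cluster, cl$members$residue)[nodes]
    expect_equal(outer(got, got, `==`), outer(oracle, oracle, `==`),
                 ignore_attr = TRUE)
  }
})

test_that("a chain of contacts forms one cluster with correct counts", {
  edges <- tibble::tibble(res_i = c(1L, 2L), res_j = c(2L, 3L),
                          min_dist = 4, area = c(30, 40), n_atom_pairs = 1L)
  cl <- build_clusters(edges)
  expect_equal(cl$totals$n_clusters, 1L)
  expect_equal(cl$clusters$n_residues, 3L)
  expect_equal(cl$clusters$n_contacts, 2L)
  expect_equal(cl$clusters$area, 70)
})

test_that("totals satisfy the area-per-contact identity at the published scale", {
  # 174 contacts summing to 7864.8 square Angstrom give 45.2 per contact
  set.seed(8)
  n <- 174
  areas <- stats::runif(n)
  areas <- areas / sum(areas) * 7864.8
  edges <- tibble::tibble(res_i = seq_len(n), res_j = seq_len(n) + 1L,
                          min_dist = 4, area = areas, n_atom_pairs = 1L)
  cl <- build_clusters(edges)
  expect_equal(cl$totals$total_contacts, 174L)
  expect_equal(cl$totals$total_area, 7864.8, tolerance = 1e-9)
  expect_equal(round(cl$totals$area_per_contact, 1), 45.2)
  expect_equal(cl$totals$area_per_contact,
               cl$totals$total_area / cl$totals$total_contacts)
})

test_that("raising the area threshold never adds contacts or merges clusters", {
  m <- ovoid_model()
  ct <- pairwise_contacts(m, n_points = 240)
  prev <- Inf
  prev_cl <- 0L
  for (th in c(0, 10, 25, 50)) {
    cl <- build_clusters(ct, area_threshold = th)
    expect_lte(cl$totals$total_contacts, prev)
    prev <- cl$totals$total_contacts
  }
})

test_that("a designed ILV core clusters across strands", {
  m <- ovoid_model()
  cl <- build_clusters(pairwise_contacts(m, n_points = 240), area_threshold = 10)
  strands <- m$strand[match(cl$members$residue, m$residue)]
  spans <- tapply(strands, cl$members$cluster,
                  function(s) length(unique(stats::na.omit(s))))
  expect_gte(max(spans), 2)
})

test_that("cluster-set comparison tabulates totals and differences", {
  m <- ovoid_model()
  ct <- pairwise_contacts(m, n_points = 240)
  a <- build_clusters(ct, area_threshold = 10)
  cmp0 <- compare_cluster_sets(a, a)
  expect_true(all(cmp0$difference == 0))
  b <- build_clusters(ct, area_threshold = 60)
  cmp <- compare_cluster_sets(a, b, labels = c("rich", "sparse"))
  expect_gte(cmp$difference[cmp$metric == "total_contacts"], 0)
  expect_gte(cmp$difference[cmp$metric == "total_area"], 0)
})
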