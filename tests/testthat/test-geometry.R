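test_that("symmetric builder produces full binary trees with homogeneous generations", {
  t1 <- build_symmetric_tree(1)
  expect_equal(n_airways(t1), 3L)
  expect_equal(n_terminals(t1), 2L)
  expect_equal(sort(t1$airways$generation), c(0L, 1L, 1L))

  t8 <- build_symmetric_tree(8, diameter_ratio = 0.81, length_ratio = 0.9)
  expect_equal(n_terminals(t8), 256L)
  af <- t8$airways
  for (g in 0:8) {
    expect_length(unique(af$diameter[af$generation == g]), 1L)
    expect_length(unique(af$length[af$generation == g]), 1L)
  }
  # every terminal at identical depth and identical cumulative path length
  trow <- match(t8$terminal_ids, af$id)
  expect_true(all(af$generation[trow] == 8L))
  path_len <- sum(2.5 * 0.9^(0:8))
  depth <- sqrt(af$x1[trow]^2 + af$y1[trow]^2 + af$z1[trow]^2)
  # path length along the (bent) tree, not euclidean depth: accumulate
  cum <- numeric(nrow(af))
  prow <- match(af$parent_id, af$id)
  for (i in order(af$generation)) {
    cum[i] <- af$length[i] + if (is.na(prow[i])) 0 else cum[prow[i]]
  }
  expect_equal(cum[trow], rep(path_len, 256), tolerance = 1e-12)
  expect_error(build_symmetric_tree(3, trachea_diameter = -1),
               "non-positive")
})

test_that("symmetric tree wall area matches the geometric series closed form", {
  t <- build_symmetric_tree(6, trachea_diameter = 0.34, trachea_length = 2.5,
                            diameter_ratio = 0.78, length_ratio = 0.85)
  expect_equal(tree_wall_area(t),
               symmetric_area_series(6, 0.34, 2.5, 0.78, 0.85),
               tolerance = 1e-12)
})

test_that("morphometry tables and tree JSON round-trip exactly", {
  tr <- airway_tree(seven_airway_table(), body_weight = 0.33)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_morphometry(tr, f)
  tr2 <- read_morphometry(f, body_weight = 0.33)
  expect_equal(tr2$airways$diameter, tr$airways$diameter, tolerance = 1e-12)
  expect_equal(tr2$airways$theta, tr$airways$theta, tolerance = 1e-12)
  expect_equal(tr2$airways$dir_x, tr$airways$dir_x, tolerance = 1e-12)
  expect_identical(tr2$terminal_ids, tr$terminal_ids)
  expect_identical(tr2$airways$generation, tr$airways$generation)

  j <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tr, j)
  tr3 <- read_tree_json(j)
  expect_equal(tr3$airways, tr$airways, tolerance = 1e-12)
  expect_identical(tr3$root_id, tr$root_id)
})

test_that("malformed airway tables are rejected and name the offending row", {
  base <- seven_airway_table()
  # self-parent
  bad <- base; bad$parent_id[2] <- bad$id[2]
  expect_error(airway_tree(bad), "cycle.*row 2")
  # two roots
  bad <- base; bad$parent_id[2] <- NA
  expect_error(airway_tree(bad), "multiple roots")
  # non-binary node: reattach 6 under 0 -> node 0 has 3 children
  bad <- base; bad$parent_id[7] <- 0L
  expect_error(airway_tree(bad), "non-binary")
  # non-positive diameter
  bad <- base; bad$diameter[3] <- 0
  expect_error(airway_tree(bad), "non-positive diameter.*row 3")
  # binary cycle disconnected from the root: 7 <-> 8 parent each other,
  # with leaf children 9 and 10 keeping every node's arity valid
  bad <- rbind(base, data.frame(id = 7:10, parent_id = c(8L, 7L, 7L, 8L),
                                diameter = 0.1, length = 0.2,
                                theta = 0.1, psi = 0))
  expect_error(airway_tree(bad), "cycle or disconnected")
})

test_that("embedding yields unit directions and the configured branch angles", {
  tr <- generate_monopodial_tree(seed = 9)
  af <- tr$airways
  norms <- sqrt(af$dir_x^2 + af$dir_y^2 + af$dir_z^2)
  expect_true(all(abs(norms - 1) < 1e-12))
  # each child axis makes its configured angle theta with the parent axis
  prow <- match(af$parent_id, af$id)
  i <- which(!is.na(prow))
  cosang <- af$dir_x[i] * af$dir_x[prow[i]] +
    af$dir_y[i] * af$dir_y[prow[i]] + af$dir_z[i] * af$dir_z[prow[i]]
  expect_equal(cosang, cos(af$theta[i]), tolerance = 1e-10)

  # 90-degree opening: sibling directions orthogonal
  ts <- build_symmetric_tree(3)
  afs <- ts$airways
  ch <- ts$children
  for (r in which(!is.na(ch[, 1L]))) {
    d1 <- unlist(afs[ch[r, 1L], c("dir_x", "dir_y", "dir_z")])
    d2 <- unlist(afs[ch[r, 2L], c("dir_x", "dir_y", "dir_z")])
    expect_lt(abs(sum(d1 * d2)), 1e-12)
  }

  # zero branching angle: children collinear with the parent
  tc <- build_symmetric_tree(2, branching_angle = 0)
  expect_true(all(abs(tc$airways$dir_z + 1) < 1e-12))
})

test_that("embedding is invariant to airway row permutation", {
  tab <- seven_airway_table()
  t1 <- airway_tree(tab)
  set.seed(4)
  t2 <- airway_tree(tab[sample(nrow(tab)), ])
  r <- match(t1$airways$id, t2$airways$id)
  expect_equal(t1$airways$dir_x, t2$airways$dir_x[r], tolerance = 1e-12)
  expect_equal(t1$airways$dir_y, t2$airways$dir_y[r], tolerance = 1e-12)
  expect_equal(t1$airways$dir_z, t2$airways$dir_z[r], tolerance = 1e-12)
  expect_equal(t1$airways$x1, t2$airways$x1[r], tolerance = 1e-12)
})

test_that("monopodial generator is reproducible and respects its cutoff", {
  a <- generate_monopodial_tree(seed = 123)
  b <- generate_monopodial_tree(seed = 123)
  expect_identical(a, b)
  c <- generate_monopodial_tree(seed = 124)
  expect_false(identical(a$airways$diameter, c$airways$diameter))

  single <- generate_monopodial_tree(seed = 1, diameter_cutoff = 0.34)
  expect_equal(n_airways(single), 1L)
  expect_equal(n_terminals(single), 1L)

  expect_error(generate_monopodial_tree(seed = 1, diameter_cutoff = 0),
               "unbounded")
  expect_error(generate_monopodial_tree(seed = 1, max_airways = 50L),
               "max_airways")
})

test_that("monopodial sample statistics emulate the configured morphometry", {
  trees <- lapply(1:20, generate_monopodial_tree)
  M <- vapply(trees, n_terminals, integer(1))
  # terminal-branch count in a band around the rat cast's 1457
  expect_gt(mean(M), 700)
  expect_lt(mean(M), 2900)
  # deep monopodial path
  expect_gt(mean(vapply(trees, function(t) max(t$airways$generation), integer(1))), 20)

  af <- do.call(rbind, lapply(trees, function(t)
    t$airways[c("generation", "diameter", "theta", "parent_id")]))
  # pooled mean diameter non-increasing with generation (small slack for
  # survivor scatter in the deepest, sparsely populated generations)
  m <- tapply(af$diameter, af$generation, mean)
  expect_true(all(diff(m[1:16]) < 0))
  expect_true(all(diff(m) < 1e-3))
  # empirical branching-angle means within 2 sd of the configured means
  ang <- abs(af$theta[!is.na(af$parent_id)]) * 180 / pi
  major <- ang[ang < 40]; minor <- ang[ang >= 40]
  expect_lt(abs(mean(major) - 19.3), 2 * 14.6)
  expect_lt(abs(mean(minor) - 60.5), 2 * 19.4)
})

test_that("bifurcation orientation matches direct projection of gravity", {
  tr <- generate_monopodial_tree(seed = 3)
  af <- tr$airways
  set.seed(11)
  for (k in 1:8) {
    g <- unit3(rnorm(3))
    po <- posture("CUSTOM", gravity = g)
    id <- sample(af$id[!is.na(tr$children[, 1L])], 1)
    o <- orient_bifurcation(tr, id, po)
    r <- match(id, af$id)
    dp <- unlist(af[r, c("dir_x", "dir_y", "dir_z")])
    expect_equal(o$gamma, asin(sum(g * dp)), tolerance = 1e-10)
    # upper daughter has the higher distal endpoint
    kids <- tr$children[r, ]
    elev <- -(af$x1[kids] * g[1] + af$y1[kids] * g[2] + af$z1[kids] * g[3])
    expect_identical(o$upper_id, af$id[kids[which.max(elev)]])
    # roll angle from the projected upper-daughter direction
    ru <- match(o$upper_id, af$id)
    du <- unlist(af[ru, c("dir_x", "dir_y", "dir_z")])
    tv <- unit3(du - dp * sum(du * dp))
    expect_equal(o$phi, asin(max(-1, min(1, -sum(g * tv)))),
                 tolerance = 1e-10)
    expect_equal(o$lambda2, af$diameter[ru] / af$diameter[r],
                 tolerance = 1e-12)
  }
  expect_error(orient_bifurcation(tr, tr$terminal_ids[1], posture("LLD")),
               "terminal")
})

test_that("posture conventions give the expected limiting pitch and roll", {
  # horizontal parent with a horizontal bifurcation plane: gamma = phi = 0
  tr <- toy_tree("single_bifurcation")
  o <- orient_bifurcation(tr, 0, posture("CUSTOM", gravity = c(1, 0, 0)))
  expect_equal(o$gamma, 0, tolerance = 1e-12)
  expect_equal(o$phi, 0, tolerance = 1e-12)
  # head-up vertical posture, zero-angle chain: |gamma| = pi/2 everywhere
  chain <- build_symmetric_tree(3, branching_angle = 0)
  vert <- posture("VERTICAL")
  for (id in chain$airways$id[!is.na(chain$children[, 1L])]) {
    o <- orient_bifurcation(chain, id, vert)
    expect_equal(abs(o$gamma), pi / 2, tolerance = 1e-12)
  }
})
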