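test_that("PD, MPD and MNTD match hand values on the toy tree", {
  t3 <- toy_tree()
  expect_equal(faith_pd(t3, c("A", "B")), 2)
  expect_equal(faith_pd(t3, c("A", "B", "C")), 5)
  expect_equal(faith_pd(t3, "A"), 0)
  expect_equal(faith_pd(t3, "A", include_root = TRUE), 2)
  expect_equal(mpd(t3, c("A", "B")), 2)
  expect_equal(mpd(t3, c("A", "B", "C")), 10 / 3)
  expect_equal(mntd(t3, c("A", "B", "C")), 8 / 3)
  expect_equal(mntd(t3, c("A", "B")), mpd(t3, c("A", "B")))
  star <- ape::read.tree(text = "(A:4,B:4,C:4,D:4);")
  expect_equal(mntd(star, c("A", "B", "C")), 8)
  expect_error(faith_pd(t3, character(0)), "nonempty")
  expect_error(faith_pd(t3, "Nope"), "not in tree")
  expect_error(mpd(t3, "A"), "at least 2")
})

test_that("observed metrics agree with picante on random trees", {
  for (s in 1:5) {
    tr <- simulate_yule_tree(15, 1, 300 + s)
    set.seed(400 + s)
    comm <- sample(tr$tip.label, 6)
    m <- matrix(1, 1, 6, dimnames = list("s1", comm))
    D <- stats::cophenetic(tr)
    expect_equal(mpd(tr, comm),
                 unname(picante::mpd(m, D[comm, comm])), tolerance = 1e-10)
    expect_equal(mntd(tr, comm),
                 unname(picante::mntd(m, D[comm, comm])), tolerance = 1e-10)
    # picante::pd forces the root; compare with include_root = TRUE
    mfull <- matrix(0, 1, 15, dimnames = list("s1", tr$tip.label))
    mfull[1, comm] <- 1
    expect_equal(faith_pd(tr, comm, include_root = TRUE),
                 picante::pd(mfull, tr)$PD, tolerance = 1e-10)
  }
})

test_that("enumeration reproduces the worked toy null moments", {
  t3 <- toy_tree()
  nm <- null_moments(t3, "PD", 2, engine = "enumerate")
  expect_equal(nm$mean, 10 / 3, tolerance = 1e-12)
  expect_equal(nm$sd, sqrt(8 / 9), tolerance = 1e-12)
  # k = n: degenerate null
  nm_full <- null_moments(t3, "PD", 3, engine = "enumerate")
  expect_equal(nm_full$sd, 0)
  expect_equal(nm_full$mean, faith_pd(t3, c("A", "B", "C")))
  expect_error(null_moments(t3, "PD", 4), "k must be")
  expect_error(null_moments(t3, "PD", 2, engine = "enumerate", cap = 1),
               "cap")
})

test_that("enumeration agrees with an independent brute-force oracle", {
  for (s in 1:3) {
    tr <- simulate_yule_tree(8, 1, 500 + s)
    for (metric in c("PD", "MPD", "MNTD")) {
      for (k in c(3, 5)) {
        nm <- null_moments(tr, metric, k, engine = "enumerate")
        oracle <- brute_null_moments(tr, metric, k)
        expect_equal(nm$mean, oracle$mean, tolerance = 1e-10)
        expect_equal(nm$sd, oracle$sd, tolerance = 1e-10)
      }
    }
  }
})

test_that("analytic null means equal enumeration means exactly", {
  tr <- simulate_yule_tree(10, 1, 77)
  for (k in 2:9) {
    for (metric in c("PD", "MPD")) {
      an <- null_moments(tr, metric, k, engine = "analytic", n_rand = 49, seed = 1)
      en <- null_moments(tr, metric, k, engine = "enumerate")
      expect_equal(an$mean, en$mean, tolerance = 1e-10)
    }
  }
  expect_error(null_moments(tr, "MNTD", 3, engine = "analytic"), "closed form")
})

test_that("Monte-Carlo moments converge to enumeration moments", {
  tr <- simulate_yule_tree(12, 1, 88)
  for (metric in c("PD", "MPD", "MNTD")) {
    for (k in c(3, 6)) {
      en <- null_moments(tr, metric, k, engine = "enumerate")
      mc <- null_moments(tr, metric, k, engine = "montecarlo",
                         n_rand = 5000, seed = 89)
      expect_lt(abs(mc$mean - en$mean), 3 * mc$sd / sqrt(5000))
    }
  }
})

test_that("SES columns follow the sign conventions and the worked example", {
  t3 <- toy_tree()
  comm <- matrix(c(1, 1, 0), 1, 3, dimnames = list("s1", c("A", "B", "C")))
  s <- ses_metrics(t3, comm, engine = "enumerate")
  expect_equal(s$PD, 2)
  expect_equal(s$MPD, 2)
  expect_equal(s$PDI, -sqrt(2), tolerance = 1e-6)
  expect_equal(s$NRI, sqrt(2), tolerance = 1e-6)

  # full pool -> null sd 0 -> SES undefined
  full <- matrix(1, 1, 3, dimnames = list("s1", c("A", "B", "C")))
  sf <- ses_metrics(t3, full, engine = "enumerate")
  expect_true(all(is.na(c(sf$PDI, sf$NRI, sf$NTI))))

  # a clade community has NRI > 0 and PDI < 0 on a larger tree
  tr <- simulate_yule_tree(20, 1, 99)
  inner <- (ape::Ntip(tr) + 2):(ape::Ntip(tr) + tr$Nnode)
  sizes <- vapply(inner, function(nd) ape::Ntip(ape::extract.clade(tr, nd)),
                  integer(1))
  nd <- inner[which(sizes >= 4 & sizes <= 8)[1]]
  cl_tips <- ape::extract.clade(tr, nd)$tip.label
  cm <- matrix(0, 1, ape::Ntip(tr), dimnames = list("s1", tr$tip.label))
  cm[1, cl_tips] <- 1
  sc <- ses_metrics(tr, cm, engine = "montecarlo", n_rand = 999, seed = 5)
  expect_gt(sc$NRI, 0)
  expect_lt(sc$PDI, 0)

  expect_error(ses_metrics(t3, comm * 2), "0/1")
})

test_that("the tree's tips define the null pool", {
  t3 <- toy_tree()
  comm <- matrix(c(1, 1, 0), 1, 3, dimnames = list("s1", c("A", "B", "C")))
  s3 <- ses_metrics(t3, comm, engine = "enumerate")
  # add a tip never observed in any community: observed metrics unchanged,
  # null moments (hence SES) change
  t4 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):3,D:5);")
  comm4 <- cbind(comm, D = 0)
  s4 <- ses_metrics(t4, comm4, engine = "enumerate")
  expect_equal(s4$PD, s3$PD)
  expect_equal(s4$MPD, s3$MPD)
  expect_false(isTRUE(all.equal(s4$NRI, s3$NRI)))
})

test_that("MNTD never exceeds MPD and PD never exceeds total tree length", {
  for (s in 1:5) {
    tr <- simulate_yule_tree(25, 1, 600 + s)
    set.seed(700 + s)
    comm <- sample(tr$tip.label, sample(3:12, 1))
    expect_lte(mntd(tr, comm), mpd(tr, comm))
    expect_lte(faith_pd(tr, comm), sum(tr$edge.length))
  }
  tr <- simulate_yule_tree(10, 1, 3)
  expect_equal(faith_pd(tr, tr$tip.label), sum(tr$edge.length))
})
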