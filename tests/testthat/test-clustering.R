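test_that("sRGB -> Lab matches the CIE reference formulas (D65)", {
  a <- array(0, c(8, 8, 3))
  a[1, 1, ] <- 1                      # white
  a[1, 2, ] <- 0                      # black
  a[1, 3, ] <- 0.5                    # mid gray
  a[1, 4, ] <- c(0.8, 0.2, 0.4)
  lab <- imgData(rgbToLab(RasterImage(a)))
  expect_equal(lab[1, 1, 1], 100, tolerance = 1e-6)
  expect_lt(max(abs(lab[1, 1, 2:3])), 0.5)
  expect_equal(lab[1, 2, ], c(0, 0, 0), tolerance = 1e-6)
  expect_equal(unname(lab[1, 3, 1]), unname(labOracle(c(0.5, 0.5, 0.5))["L"]),
               tolerance = 1e-3)
  expect_equal(unname(lab[1, 4, ]), unname(labOracle(c(0.8, 0.2, 0.4))),
               tolerance = 1e-2)
  # gray input is replicated before conversion: a/b come out ~0
  g <- rgbToLab(RasterImage(matrix(0.3, 8, 8)))
  expect_equal(nChannels(g), 3L)
  expect_lt(max(abs(imgData(g)[, , 2:3])), 1e-6)
  expect_warning(rgbToLab(g), "already")
})

test_that("k-means: closed forms, brute-force optimum, invariances", {
  set.seed(31)
  pts <- matrix(rnorm(40), 20, 2)
  cs1 <- kmeansCluster(pts, 1L)
  expect_equal(clusterCenters(cs1)[1, ], colMeans(pts), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(objectiveValue(cs1), sum(sweep(pts, 2, colMeans(pts))^2),
               tolerance = 1e-10)

  quad <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  cs2 <- kmeansCluster(quad, 2L)
  expect_equal(sort(clusterCenters(cs2)[, 1]), c(0, 10), ignore_attr = TRUE)
  expect_equal(clusterCenters(cs2)[, 2], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(clusterLabels(cs2)[1], clusterLabels(cs2)[2])
  expect_equal(clusterLabels(cs2)[3], clusterLabels(cs2)[4])
  expect_false(clusterLabels(cs2)[1] == clusterLabels(cs2)[3])
  expect_equal(objectiveValue(cs2), bruteForceKmeans2(quad)$J, tolerance = 1e-12)

  # permuting the input only permutes the labels
  perm <- c(3, 1, 4, 2)
  csP <- kmeansCluster(quad[perm, ], 2L)
  expect_equal(objectiveValue(csP), objectiveValue(cs2))
  expect_equal(length(unique(paste(clusterLabels(cs2)[perm],
                                   clusterLabels(csP)))), 2L)

  expect_error(kmeansCluster(quad, 5L), "exceed")
  expect_error(kmeansCluster(rbind(c(1, 1), c(1, 1)), 2L), "distinct")
})

test_that("k-means objective never increases from its initialization", {
  set.seed(77)
  for (run in 1:50) {
    pts <- matrix(rnorm(60), 30, 2)
    g <- SPFKMC:::rowGroups(pts)
    sd0 <- run * 13L
    init <- SPFKMC:::withLocalSeed(sd0, g$uniq[sample.int(nrow(g$uniq), 3L), ])
    d2 <- outer(rowSums(pts^2), rowSums(init^2), "+") - 2 * pts %*% t(init)
    jInit <- sum(apply(d2, 1, min))
    cs <- kmeansCluster(pts, 3L, seed = sd0, nstart = 1L)
    expect_lte(objectiveValue(cs), jInit + 1e-9)
  }
})

test_that("fuzzy C-means: degenerate, symmetric and singular cases", {
  set.seed(41)
  pts <- matrix(rnorm(30), 15, 2)
  mm1 <- fcmCluster(pts, 1L)
  expect_true(all(memberships(mm1) == 1))
  expect_equal(clusterCenters(mm1)[1, ], colMeans(pts), tolerance = 1e-6,
               ignore_attr = TRUE)

  # two tight, far-apart triplets: defuzzified FCM equals the optimal
  # bipartition found by exhaustive search
  tri <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),
               c(30, 30), c(30.1, 30), c(30, 30.1))
  mm2 <- fcmCluster(tri, 2L, m = 2)
  expect_lt(max(abs(rowSums(memberships(mm2)) - 1)), 1e-9)
  cs <- defuzzify(mm2, tri)
  bf <- bruteForceKmeans2(tri)
  expect_equal(clusterLabels(cs)[1:3], rep(clusterLabels(cs)[1], 3))
  expect_equal(clusterLabels(cs)[4:6], rep(clusterLabels(cs)[4], 3))
  expect_equal(objectiveValue(cs), bf$J, tolerance = 1e-6)

  # an equidistant point splits 50/50 under m = 2 (converged centers are
  # symmetric about it)
  line <- rbind(c(0, 0), c(1, 0), c(0.5, 0))
  mmS <- fcmCluster(line, 2L, m = 2, maxIter = 500L, tol = 1e-10)
  expect_equal(memberships(mmS)[3, ], c(0.5, 0.5), tolerance = 1e-3,
               ignore_attr = TRUE)

  # singularity rule: a point exactly on a center is one-hot (initial
  # centers are data points, so evaluate memberships before any update)
  mm0 <- fcmCluster(line, 2L, m = 2, maxIter = 0L)
  ctr0 <- clusterCenters(mm0)
  u0 <- memberships(mm0)
  for (i in seq_len(nrow(line))) for (j in 1:2)
    if (all(line[i, ] == ctr0[j, ])) {
      expect_equal(u0[i, j], 1)
      expect_equal(sum(u0[i, ]), 1)
    }
  expect_error(fcmCluster(pts, 2L, m = 1), "m must be > 1")
})

test_that("fcm centers agree with the e1071 reference on separated data", {
  set.seed(52)
  pts <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
               matrix(rnorm(40, 8, 0.3), 20, 2))
  mm <- fcmCluster(pts, 2L, m = 2, seed = 1L)
  ref <- e1071::cmeans(pts, centers = 2, m = 2)
  ours <- clusterCenters(mm)[order(clusterCenters(mm)[, 1]), ]
  theirs <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(ours, theirs, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("cluster images partition the source support and conserve mass", {
  set.seed(61)
  m <- matrix(runif(96, 0.1, 1), 8, 12)
  feats <- cbind(as.vector(m))
  cs <- kmeansCluster(feats, 3L, dims = c(8L, 12L))
  imgs <- clusterImages(cs, grayRaster(m))
  expect_length(imgs, 3L)
  supports <- lapply(imgs, function(im) imgData(im)[, , 1] != 0)
  for (i in 1:2) for (j in (i + 1):3)
    expect_false(any(supports[[i]] & supports[[j]]))   # pairwise disjoint
  expect_true(all(Reduce(`|`, supports)))              # union covers all
  total <- Reduce(`+`, lapply(imgs, function(im) imgData(im)[, , 1]))
  expect_equal(total, m, tolerance = 1e-12)            # mass conserved

  # direct masking example: left half one cluster, right half the other
  m2 <- matrix(rep(c(0.2, 0.8), each = 32), 8, 8)
  cs2 <- kmeansCluster(cbind(as.vector(m2)), 2L, dims = c(8L, 8L))
  imgs2 <- clusterImages(cs2, grayRaster(m2))
  lows <- which(vapply(imgs2, function(i) max(imgData(i)), 1) == 0.2)
  expect_true(all(imgData(imgs2[[lows]])[, 1:4, 1] == 0.2))
  expect_true(all(imgData(imgs2[[lows]])[, 5:8, 1] == 0))
})

test_that("cluster selection: manual picks, auto ranks by ROI support", {
  # disjoint supports of sizes 10 / 50 / 30 (10 pixels belong to none)
  lab <- rep(c(1L, 2L, 3L, 0L), c(10, 50, 30, 10))
  imgs <- lapply(1:3, function(j) {
    m <- matrix(0, 10, 10); m[lab == j] <- 0.9
    grayRaster(m)
  })
  man <- selectClusters(imgs, "manual", indices = 3L)
  expect_length(man, 1L)
  expect_equal(attr(man, "indices"), 3L)
  expect_error(selectClusters(imgs, "manual", indices = 5L), "out of range")
  expect_error(selectClusters(imgs, "manual"), "requires")

  auto <- selectClusters(imgs, "auto")
  expect_equal(attr(auto, "indices"), c(2L, 3L))

  roi <- BinaryMask(matrix(rep(c(TRUE, FALSE), c(10, 90)), 10, 10))
  one <- selectClusters(imgs, "auto", roi = roi)
  expect_equal(attr(one, "indices")[1], 1L)  # all ROI pixels live in cluster 1
})
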