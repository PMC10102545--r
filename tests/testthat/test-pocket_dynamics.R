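chain_traj <- function(frames, n = 6, timestep_ns = 0.1) {
  a <- protein_atoms(n)
  a$resname <- c("SER", "ASP", "HIS", rep("ALA", n - 3))[seq_len(n)]
  traj_from_frames(frames, a, timestep_ns)
}

base_coords <- function(n = 6) cbind(seq_len(n) * 3.8, 0, 0)

test_that("superpose_frames undoes pure translations and known rotations", {
  set.seed(2)
  b <- matrix(rnorm(18, sd = 5), 6, 3)
  tr <- chain_traj(list(b, sweep(b, 2, c(5, -3, 2), `+`)))
  sup <- superpose_frames(tr, selection = 1:6)
  expect_equal(sup$coords[2, , ], sup$coords[1, , ], tolerance = 1e-6)

  mo <- random_rigid_motion(7)
  tr2 <- chain_traj(list(b, sweep(b %*% t(mo$R), 2, mo$t, `+`)))
  sup2 <- superpose_frames(tr2, selection = 1:6)
  expect_equal(sup2$coords[2, , ], sup2$coords[1, , ], tolerance = 1e-6)
  expect_error(superpose_frames(tr2, selection = integer()),
               class = "ltk_empty_selection")
})

test_that("superposition never increases selection RMSD to frame 1", {
  set.seed(3)
  b <- matrix(rnorm(18, sd = 4), 6, 3)
  frames <- list(b, b + matrix(rnorm(18, sd = 0.6), 6, 3))
  tr <- chain_traj(frames)
  sup <- superpose_frames(tr, selection = 1:6)
  rmsd <- function(x, y) sqrt(mean(rowSums((x - y)^2)))
  expect_lte(rmsd(sup$coords[2, , ], frames[[1]]),
             rmsd(frames[[2]], frames[[1]]) + 1e-12)
})

test_that("flexibility profile is the RMSF about the time mean", {
  b <- base_coords()
  # residue 2 alternates between two points 2 apart -> rmsf = 1
  f2 <- b; f2[2, 2] <- 2
  tr <- chain_traj(list(b, f2, b, f2))
  prof <- flexibility_profile(tr)
  expect_equal(prof$rmsf[prof$resnum == 2], 1)
  expect_equal(prof$rmsf[prof$resnum == 5], 0)

  set.seed(6)
  frames <- lapply(1:8, function(i) b + matrix(rnorm(18, sd = 0.3), 6, 3))
  trr <- chain_traj(frames)
  prof2 <- flexibility_profile(trr)
  # brute-force accumulation per residue
  for (r in 1:6) {
    p <- t(vapply(frames, function(f) f[r, ], numeric(3)))
    mu <- colMeans(p)
    expect_equal(prof2$rmsf[prof2$resnum == r],
                 sqrt(mean(rowSums(sweep(p, 2, mu)^2))), tolerance = 1e-9)
  }
})

test_that("flexible_regions finds maximal runs above a strict cutoff", {
  prof <- data.frame(chain = "A", resnum = 70:110, icode = "",
                     resname = "ALA", rmsf = 0.01)
  prof$rmsf[prof$resnum %in% 79:106] <- 0.05
  class(prof) <- c("FlexibilityProfile", "data.frame")
  reg <- flexible_regions(prof, 0.025)
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$from, reg$to), c(79L, 106L))

  expect_equal(nrow(flexible_regions(prof, 1)), 0L)

  # coverage grows as the cutoff shrinks; equals brute-force run detection
  set.seed(12)
  prof$rmsf <- runif(41, 0, 0.06)
  r1 <- flexible_regions(prof, 0.01); r2 <- flexible_regions(prof, 0.03)
  cov <- function(r) unlist(mapply(seq, r$from, r$to, SIMPLIFY = FALSE))
  expect_true(all(cov(r2) %in% cov(r1)))
  expect_setequal(cov(r2), prof$resnum[prof$rmsf > 0.03])
})

test_that("dihedral_series hits analytic cases and the brute-force oracle", {
  mk <- function(p1, p2, p3, p4)
    chain_traj(list(rbind(p1, p2, p3, p4, c(9, 9, 9), c(10, 10, 10))))
  anch <- sprintf("A:%d", 1:4)
  cis <- mk(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(dihedral_series(cis, anch)$values, 0)
  trans <- mk(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(abs(dihedral_series(trans, anch)$values), 180)
  # staggered butane-like: +-60
  g60 <- mk(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
            c(1, cos(pi / 3), sin(pi / 3)))
  expect_equal(abs(dihedral_series(g60, anch)$values), 60, tolerance = 1e-9)

  set.seed(31)
  for (i in 1:20) {
    P <- matrix(rnorm(12, sd = 3), 4, 3)
    tr <- mk(P[1, ], P[2, ], P[3, ], P[4, ])
    expect_equal(dihedral_series(tr, anch)$values,
                 oracle_dihedral(P[1, ], P[2, ], P[3, ], P[4, ]),
                 tolerance = 1e-9)
  }
  # collinear p2-p3 with p1 -> undefined
  col <- mk(c(2, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_true(is.na(dihedral_series(col, anch)$values))
})

test_that("angle_series and distance_series hit analytic cases and oracles", {
  mk <- function(p1, p2, p3)
    chain_traj(list(rbind(p1, p2, p3, c(9, 9, 9), c(10, 10, 10), c(11, 11, 11))))
  anch3 <- sprintf("A:%d", 1:3)
  expect_equal(angle_series(mk(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)),
                            anch3)$values, 90)
  expect_equal(angle_series(mk(c(1, 0, 0), c(0, 0, 0), c(-2, 0, 0)),
                            anch3)$values, 180)
  set.seed(13)
  for (i in 1:15) {
    P <- matrix(rnorm(9, sd = 2), 3, 3)
    expect_equal(angle_series(mk(P[1, ], P[2, ], P[3, ]), anch3)$values,
                 oracle_angle(P[1, ], P[2, ], P[3, ]), tolerance = 1e-9)
    expect_equal(distance_series(mk(P[1, ], P[2, ], P[3, ]),
                                 anch3[1:2])$values,
                 sqrt(sum((P[1, ] - P[2, ])^2)), tolerance = 1e-9)
  }
  expect_equal(distance_series(mk(c(0, 0, 0), c(1, 0, 0), c(5, 5, 5)),
                               anch3[1:2])$values, 1)
  expect_true(is.na(angle_series(mk(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                                 anch3)$values))
})

test_that("descriptors are invariant under rigid motion; dihedral flips under mirror", {
  set.seed(77)
  frames <- lapply(1:4, function(i) matrix(rnorm(18, sd = 4), 6, 3))
  tr <- chain_traj(frames)
  mo <- random_rigid_motion(5)
  tr2 <- apply_rigid(tr, mo)
  anch <- sprintf("A:%d", 1:4)
  expect_equal(dihedral_series(tr2, anch)$values,
               dihedral_series(tr, anch)$values, tolerance = 1e-9)
  expect_equal(angle_series(tr2, anch[1:3])$values,
               angle_series(tr, anch[1:3])$values, tolerance = 1e-9)
  expect_equal(distance_series(tr2, anch[1:2])$values,
               distance_series(tr, anch[1:2])$values, tolerance = 1e-9)

  mirror <- tr
  mirror$coords <- -mirror$coords
  expect_equal(dihedral_series(mirror, anch)$values,
               -dihedral_series(tr, anch)$values, tolerance = 1e-9)
  expect_equal(angle_series(mirror, anch[1:3])$values,
               angle_series(tr, anch[1:3])$values, tolerance = 1e-9)
})

test_that("contact_frequency counts frames with any-atom contact per residue", {
  pa <- protein_atoms(3)
  sa <- substrate_atoms("PC")
  # substrate parked 5 A from residue 1 (at origin) for all frames
  frames <- lapply(1:4, function(f)
    rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0), c(5, 0, 0)))
  tr <- traj_from_frames(frames, rbind(pa, sa))
  cm <- contact_frequency(tr, "PC", cutoff = 8, highlight = 3)
  expect_equal(cm$freq_PC, c(4L, 0L, 0L))
  expect_equal(cm$highlight_PC, c(TRUE, FALSE, FALSE))

  # far substrate -> all zero
  frames0 <- lapply(1:4, function(f)
    rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0), c(300, 0, 0)))
  cm0 <- contact_frequency(traj_from_frames(frames0, rbind(pa, sa)), "PC")
  expect_true(all(cm0$freq_PC == 0))

  # cutoff 0 -> zeros; huge cutoff -> n_frames everywhere
  tr2 <- traj_from_frames(frames, rbind(pa, sa))
  expect_true(all(contact_frequency(tr2, "PC", cutoff = 1e-9)$freq_PC == 0))
  expect_true(all(contact_frequency(tr2, "PC", cutoff = 1e9)$freq_PC == 4L))
})

test_that("contact_frequency equals a brute-force all-pairs scan", {
  set.seed(41)
  pa <- protein_atoms(8)
  sa <- rbind(substrate_atoms(c("PC", "PC", "DHA-TAG")))
  nf <- 6
  frames <- lapply(seq_len(nf), function(f)
    matrix(runif(11 * 3, 0, 25), 11, 3))
  tr <- traj_from_frames(frames, rbind(pa, sa))
  cm <- contact_frequency(tr, c("PC", "DHA-TAG"), cutoff = 8)
  for (cl in c("PC", "DHA-TAG")) {
    sidx <- which(tr$atoms$mol_class == cl)
    for (r in 1:8) {
      cnt <- 0L
      for (f in seq_len(nf)) {
        dmin <- min(vapply(sidx, function(j)
          sqrt(sum((frames[[f]][r, ] - frames[[f]][j, ])^2)), numeric(1)))
        if (dmin < 8) cnt <- cnt + 1L
      }
      expect_equal(cm[[paste0("freq_", cl)]][cm$resnum == r], cnt)
    }
  }
  # cross-batch averaging
  avg <- average_contact_maps(list(cm, cm))
  expect_equal(avg$mean_freq_PC, cm$freq_PC)
})
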