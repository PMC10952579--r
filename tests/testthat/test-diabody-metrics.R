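test_that("diabody descriptors are invariant under global rigid motion", {
  set.seed(41)
  db <- toy_diabody_fixture(dihedral = 77, angle = 95)
  ref <- build_reference_frame(db$model, db$defn, "A")
  d0 <- diabody_dihedral(db$model, db$defn)
  a0 <- diabody_angle(db$model, db$defn)
  p0 <- sphere_projection(db$model, db$defn, ref, "A")
  for (i in 1:10) {
    m <- random_rigid_copy(db$model)
    expect_lt(abs(diabody_dihedral(m, db$defn) - d0), 1e-6)
    expect_lt(abs(diabody_angle(m, db$defn) - a0), 1e-6)
    p <- sphere_projection(m, db$defn, ref, "A")
    expect_lt(abs(p$vh$theta - p0$vh$theta), 1e-6)
    expect_lt(abs(p$vh$phi - p0$vh$phi), 1e-6)
    expect_lt(abs(p$vl$theta - p0$vl$theta), 1e-6)
    expect_lt(abs(p$vl$phi - p0$vl$phi), 1e-6)
  }
})

test_that("diabody_angle is symmetric in site order", {
  db <- toy_diabody_fixture(dihedral = 40, angle = 130)
  a <- pseudo_dyad_axis(db$model, db$defn, "A")
  b <- pseudo_dyad_axis(db$model, db$defn, "B")
  expect_identical(angle_between(a, b), angle_between(b, a))
})

test_that("pseudo-dyad axis is equivariant and stable under coordinate noise", {
  set.seed(42)
  fv <- build_toy_fv(toy_fv_spec())
  R <- random_rotation(); t <- rnorm(3, 0, 12)
  m2 <- dbgeom:::set_coords(fv$model,
                            sweep(coords(fv$model) %*% t(R), 2, t, "+"))
  ax2 <- pseudo_dyad_axis(m2, fv$defn, "A")
  expect_lt(max(abs(ax2 - as.numeric(R %*% fv$truth$dyad_axis))), 1e-6)

  # sigma = 0.2 A coordinate noise moves the axis by well under 2 degrees
  for (i in 1:100) {
    noisy <- dbgeom:::set_coords(
      fv$model, coords(fv$model) +
        matrix(rnorm(3 * nrow(fv$model$atoms), 0, 0.2), ncol = 3))
    axn <- pseudo_dyad_axis(noisy, fv$defn, "A")
    expect_lt(angle_between(axn, fv$truth$dyad_axis), 2)
  }
})

test_that("reference-frame construction is idempotent and pose-invariant", {
  set.seed(43)
  db <- toy_diabody_fixture(dihedral = 100, angle = 80)
  ref1 <- build_reference_frame(db$model, db$defn, "A")
  # canonical invariants
  expect_lt(max(abs(ref1$transform$rotation %*%
                      pseudo_dyad_axis(db$model, db$defn, "A") - c(0, 0, 1))),
            1e-6)
  ch <- ref1$centroid_vh
  expect_lt(abs(atan2(ch[2], ch[1])), 1e-9)   # V_H centroid at theta = 0

  # rebuilding from the canonicalized coordinates is the identity
  canon <- dbgeom:::set_coords(
    db$model, apply_transform(ref1$transform, coords(db$model)))
  ref2 <- build_reference_frame(canon, db$defn, "A")
  expect_lt(max(abs(ref2$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(ref2$transform$translation)), 1e-6)

  # two random poses give atom-wise identical reference frames
  refs <- lapply(1:2, function(i) {
    build_reference_frame(random_rigid_copy(db$model), db$defn, "A")
  })
  expect_lt(max(abs(refs[[1]]$coords - refs[[2]]$coords)), 1e-6)
  expect_lt(max(abs(ref1$coords - refs[[1]]$coords)), 1e-6)
})

test_that("reference frame round-trips through its PDB export", {
  db <- toy_diabody_fixture(dihedral = 60, angle = 120)
  ref <- build_reference_frame(db$model, db$defn, "A")
  tmp <- tempfile(fileext = ".pdb")
  write_reference_frame(ref, tmp)
  got <- read_reference_frame(tmp)
  expect_equal(got$n_vh, ref$n_vh)
  expect_equal(got$site, ref$site)
  expect_lt(max(abs(got$coords - ref$coords)), 1e-3 + 1e-9)
  expect_lt(max(abs(got$centroid_vh - ref$centroid_vh)), 1e-3)
})

test_that("sphere projection matches the generator's analytic placement", {
  db <- toy_diabody_fixture(dihedral = 135, angle = 100)
  ref <- build_reference_frame(db$model, db$defn, "A")
  tt <- toy_projection_truth(db$truth)
  for (s in c("A", "B")) {
    p <- sphere_projection(db$model, db$defn, ref, s)
    row <- tt[tt$aligned_site == s, ]
    expect_lt(abs(p$vh$theta - row$theta_vh), 1e-6)
    expect_lt(abs(p$vh$phi - row$phi_vh), 1e-6)
    expect_lt(abs(p$vl$theta - row$theta_vl), 1e-6)
    expect_lt(abs(p$vl$phi - row$phi_vl), 1e-6)
  }
})

test_that("exact-C2 diabody gives coinciding dual projections", {
  dc <- build_toy_diabody_c2(toy_fv_spec())
  ref <- build_reference_frame(dc$model, dc$defn, "A")
  pA <- sphere_projection(dc$model, dc$defn, ref, "A")
  pB <- sphere_projection(dc$model, dc$defn, ref, "B")
  for (dm in c("vh", "vl")) {
    expect_lt(abs(pA[[dm]]$theta - pB[[dm]]$theta), 1e-6)
    expect_lt(abs(pA[[dm]]$phi - pB[[dm]]$phi), 1e-6)
  }
})

test_that("dual_projection emits 2 rows per frame for projections, 1 for angles", {
  base <- toy_diabody_fixture()
  st <- sample_trajectory(ensemble_spec(10, seed = 44), base)
  ref <- build_reference_frame(base$model, base$defn, "A")
  dp <- dual_projection(st$traj, st$defn, ref)
  expect_equal(nrow(dp$projections), 20L)
  expect_equal(nrow(dp$angles), 10L)
  expect_setequal(unique(dp$projections$aligned_site), c("A", "B"))
})

test_that("a trajectory of identical frames has zero descriptor variance", {
  db <- toy_diabody_fixture(dihedral = 50, angle = 70)
  tr <- trajectory(list(db$model, db$model, db$model))
  ref <- build_reference_frame(db$model, db$defn, "A")
  dp <- dual_projection(tr, db$defn, ref)
  expect_equal(var(dp$angles$dihedral), 0)
  expect_equal(var(dp$angles$diabody_angle), 0)
  expect_equal(var(dp$projections$theta_vh[dp$projections$aligned_site == "A"]), 0)
})

test_that("bimodal dihedral ensembles reproduce component means per label", {
  base <- toy_diabody_fixture()
  spec <- ensemble_spec(300, seed = 45,
                        dihedral = list(means = c(60, 150), kappas = c(50, 50),
                                        weights = c(0.5, 0.5)))
  st <- sample_trajectory(spec, base)
  ref <- build_reference_frame(base$model, base$defn, "A")
  dp <- dual_projection(st$traj, st$defn, ref)
  for (k in 1:2) {
    sel <- st$truth$dihedral_label == k
    expect_lt(abs(dbgeom:::wrap180(
      circular_mean(dp$angles$dihedral[sel]) - c(60, 150)[k])), 2.5)
  }
})
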