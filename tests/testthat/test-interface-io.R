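test_that("configuration round-trips through YAML with overrides", {
  cfg <- load_config()
  expect_equal(cfg$kinetics$alpha, 3.33e-2)
  expect_equal(cfg$wall$tau1, 10)
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, path)
  cfg2 <- load_config(path)
  expect_equal(cfg2, cfg)
  cfg3 <- load_config(path, overrides = c("flow.V0=6.5", "geometry.H=0.5"))
  expect_equal(cfg3$flow$V0, 6.5)
  expect_equal(cfg3$geometry$H, 0.5)
  expect_error(load_config(path, overrides = "flow.bogus=1"), "unknown config key")
  expect_error(load_config(path, overrides = "garbage"), "section.key=value")
  ## unknown keys in the file are rejected with the key named
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("wall:\n  muX: 1", bad)
  expect_error(load_config(bad), "muX")
})

test_that("config maps onto validated parameters and numerics", {
  cfg <- load_config(overrides = c("flow.V0=6.5", "geometry.H=0.5",
                                   "numerics.resolution=16"))
  setup <- config_to_setup(cfg)
  expect_s3_class(setup$params, "stenoclot_params")
  expect_equal(nondimensionalize(setup$params)$Re, 130)
  expect_equal(setup$config$resolution, 16)
})

test_that("VTK and CSV writers emit parseable artifacts", {
  p <- default_parameters(H = 0.3, Lx = 1)
  mesh <- build_mesh(p, 10)
  dir <- withr::local_tempdir()
  v <- file.path(dir, "f.vtk")
  write_vtk(mesh, list(foo = mesh$cx, bar = mesh$cy), v)
  lines <- readLines(v)
  expect_equal(lines[1], "# vtk DataFile Version 2.0")
  expect_true(any(grepl("^POINTS", lines)))
  expect_true(any(grepl("SCALARS foo double 1", lines)))
  npts <- as.integer(strsplit(grep("^POINTS", lines, value = TRUE), " ")[[1]][2])
  expect_equal(npts, (mesh$nx + 1) * (mesh$ny + 1))
  cpath <- file.path(dir, "f.csv")
  write_fields_csv(mesh, list(foo = mesh$cx), cpath)
  df <- utils::read.csv(cpath)
  expect_equal(nrow(df), mesh$ncell)
  expect_equal(df$foo, mesh$cx)
  mp <- write_mesh_csv(mesh, file.path(dir, "m"))
  expect_true(all(file.exists(mp)))
  bf <- utils::read.csv(mp[2])
  expect_setequal(unique(bf$patch), c("inlet", "outlet", "wall_upper", "wall_lower"))
})

test_that("run_simulation produces a complete, deterministic manifest", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- load_config(overrides = c(
    "flow.V0=3", "geometry.H=0.3", "geometry.Lx=2", "geometry.d=0.3",
    "numerics.resolution=10", "numerics.t_max=40", "numerics.dt=0.05"))
  man1 <- run_simulation(cfg, out_dir = dir1)
  expect_s3_class(man1, "stenoclot_manifest")
  expect_true(all(file.exists(file.path(dir1, man1$artifacts))))
  expect_true(man1$regime %in% c("I", "II"))
  ## determinism: identical configuration -> identical scalar series
  man2 <- run_simulation(cfg, out_dir = dir2)
  s1 <- readLines(file.path(dir1, "max_nw.tsv"))
  s2 <- readLines(file.path(dir2, "max_nw.tsv"))
  expect_identical(s1, s2)
  expect_identical(man1$config_hash, man2$config_hash)
  ## config echo reruns identically end-to-end
  cfg_echo <- load_config(file.path(dir1, "config.yaml"))
  expect_equal(config_to_setup(cfg_echo)$params, config_to_setup(cfg)$params)
})

test_that("the full verification-fixture suite passes", {
  rep <- verify_fixtures(fast = TRUE)
  expect_true(all(rep$pass), info = paste(utils::capture.output(print(rep)),
                                          collapse = "\n"))
})
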