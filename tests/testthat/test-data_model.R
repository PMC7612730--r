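test_that("cell tables parse, validate and round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(image_id = "img1", patient_id = "P1", cell_id = 1:3,
                   x_um = c(1, 2.5, 3), y_um = c(4, 5, 6.25),
                   M1 = c(0, 1.5, 2), M2 = c(3, 0, 1))
  write.csv(df, path, row.names = FALSE)
  tab <- read_cell_table(path, panel = c("M1", "M2"))
  expect_s3_class(tab, "cell_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(panel_of(tab), c("M1", "M2"))
  expect_true(all(c("compartment", "hot_pixel_flag") %in% names(tab)))

  out <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(tab, out)
  expect_true(file.exists(paste0(out, ".json")))
  tab2 <- read_cell_table(out, panel = c("M1", "M2"))
  expect_identical(tab2$image_id, tab$image_id)
  expect_identical(as.integer(tab2$cell_id), as.integer(tab$cell_id))
  expect_equal(tab2$x_um, tab$x_um, tolerance = 1e-9)
  expect_equal(tab2$M1, tab$M1, tolerance = 1e-9)
})

test_that("schema and validity violations are rejected by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(image_id = "i", patient_id = "p", cell_id = 1,
                       y_um = 1, M1 = 1), path, row.names = FALSE)
  expect_error(read_cell_table(path, "M1"), "x_um")
  base <- data.frame(image_id = "i", patient_id = "p", cell_id = 1:2,
                     x_um = 1:2, y_um = 1:2)
  expect_error(cell_table(cbind(base, M1 = c(1, -3)), "M1"), "row 2")
  bad <- cbind(base, M1 = 1:2); bad$cell_id <- c(1, 1)
  expect_error(cell_table(bad, "M1"), "unique")
  expect_error(read_cell_table("no/such/file.csv", "M1"), "not found")
})

test_that("hot-pixel filtering removes flagged rows and is idempotent", {
  tab <- toy_cells(10)
  tab$hot_pixel_flag[c(3, 7)] <- TRUE
  out <- suppressMessages(filter_cells(tab))
  expect_equal(nrow(out), 8L)
  expect_false(any(out$hot_pixel_flag))
  expect_equal(nrow(suppressMessages(filter_cells(out))), 8L)

  clean <- toy_cells(4)
  expect_equal(nrow(filter_cells(clean)), 4L)

  allbad <- toy_cells(3)
  allbad$hot_pixel_flag <- TRUE
  expect_warning(out2 <- suppressMessages(filter_cells(allbad)), "all cells")
  expect_equal(nrow(out2), 0L)
})

test_that("mask overlap flags containment and inclusive contact distance", {
  ## region occupies columns 1..5 (x in [0,5]); boundary centers at x=4.5
  grid <- matrix(0L, 40, 40)
  grid[, 1:5] <- 1L
  mask <- mask_grid("img1", "tumor", grid, pixel_size_um = 1)
  tab <- toy_cells(4, x = c(2.5, 12.5, 12.6, 30.5),
                   y = c(10.5, 10.5, 10.5, 10.5))
  out <- attach_mask_overlap(tab, mask, contact_um = 8)
  expect_identical(out$in_tumor_mask, c(TRUE, TRUE, FALSE, FALSE))

  ## vessel kind sets the other flag
  vmask <- mask_grid("img1", "vessel", grid, 1)
  out2 <- attach_mask_overlap(tab, vmask, contact_um = 8)
  expect_identical(out2$in_vessel_mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(out2$in_tumor_mask))

  expect_error(attach_mask_overlap(toy_cells(2, image_id = "other"), mask),
               "image_id")
})

test_that("mask overlap is monotone in the contact distance", {
  set.seed(9)
  grid <- matrix(0L, 50, 50)
  grid[20:30, 20:30] <- 1L
  mask <- mask_grid("img1", "tumor", grid, 1)
  tab <- toy_cells(40, x = runif(40, 0, 50), y = runif(40, 0, 50))
  prev <- rep(FALSE, 40)
  for (d in c(0, 2, 5, 10, 20)) {
    cur <- attach_mask_overlap(tab, mask, contact_um = d)$in_tumor_mask
    expect_true(all(cur[prev]))  # enlarging never unsets
    prev <- cur
  }
})

test_that("masks round-trip through CSV grids with contiguous ids", {
  grid <- matrix(0L, 10, 12)
  grid[2:4, 3:5] <- 5L  # non-contiguous id gets relabeled to 1
  mask <- mask_grid("im", "vessel", grid, 2)
  expect_equal(sort(unique(as.vector(mask$grid))), c(0L, 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mask(mask, path)
  back <- read_mask(path, "im", "vessel", pixel_size_um = 2)
  expect_identical(back$grid, mask$grid)
  expect_equal(dim(back$grid), c(10L, 12L))
})

test_that("clinical and alteration tables validate on read", {
  clin <- data.frame(patient_id = c("P1", "P2"),
                     er_status = c("pos", "neg"),
                     her2_status = c("neg", "unknown"),
                     dss_time_months = c(30, 12.5), dss_event = c(1, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(clin, path, row.names = FALSE)
  expect_silent(read_clinical(path))
  bad <- clin; bad$dss_time_months[1] <- 0
  expect_error(validate_clinical(bad), "dss_time")
  bad2 <- clin; bad2$patient_id <- c("P1", "P1")
  expect_error(validate_clinical(bad2), "duplicate")

  alt <- data.frame(patient_id = c("P1", "P2"), TP53_mut = c(1, 0),
                    MYC_gain = c(0, 1))
  apath <- withr::local_tempfile(fileext = ".csv")
  write.csv(alt, apath, row.names = FALSE)
  m <- read_alteration_matrix(apath)
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(rownames(m), c("P1", "P2"))
})
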