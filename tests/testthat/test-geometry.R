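test_that("default model carries 150 strands, 75 per side", {
  model <- default_model()
  expect_length(model$strands, 150)
  expect_equal(unname(table(model$strand_table$side)), c(75L, 75L),
               ignore_attr = TRUE)
})

test_that("symmetric geometry mirrors exactly across the midsagittal plane", {
  model <- default_model()
  tab <- model$strand_table
  for (muscle in muscle_parts()) {
    r <- tab$index[tab$muscle == muscle & tab$side == "right"]
    l <- tab$index[tab$muscle == muscle & tab$side == "left"]
    for (k in seq_along(r)) {
      pr <- model$strands[[r[k]]]$path
      pl <- model$strands[[l[k]]]$path
      expect_equal(pl, pr %*% diag(c(1, -1, 1)), tolerance = 0,
                   ignore_attr = TRUE)
    }
  }
  expect_equal(model$condyle_left, model$condyle_right * c(1, -1, 1))
  expect_equal(model$bite_points$molar_left,
               model$bite_points$molar_right * c(1, -1, 1))
})

test_that("model building is deterministic; jitter is seed-controlled", {
  g1 <- synthetic_jaw_geometry()
  g2 <- synthetic_jaw_geometry()
  expect_identical(g1, g2)
  j1 <- synthetic_jaw_geometry(jitter_sd = 0.5, seed = 7L)
  j2 <- synthetic_jaw_geometry(jitter_sd = 0.5, seed = 7L)
  j3 <- synthetic_jaw_geometry(jitter_sd = 0.5, seed = 8L)
  expect_identical(j1, j2)
  expect_false(identical(j1$muscles[[1]]$origin_c, j3$muscles[[1]]$origin_c))
  # jittered-but-symmetric geometry still mirrors exactly
  m1 <- j1$muscles[[1]]; ml <- j1$muscles[[10]]
  expect_equal(ml$origin_c, m1$origin_c * c(1, -1, 1))
})

test_that("attachment tables round-trip losslessly through CSV", {
  model <- default_model()
  path <- withr::local_tempfile(fileext = ".csv")
  write_attachments(model, path)
  tab <- read_attachments(path)
  orig <- as_attachment_table(model)
  orig <- dplyr::arrange(orig, muscle, side, strand, ordinal)
  expect_equal(tab$x, orig$x, tolerance = 1e-12)
  expect_equal(tab$y, orig$y, tolerance = 1e-12)
  expect_equal(tab$z, orig$z, tolerance = 1e-12)
  expect_equal(tab$frame, orig$frame)
  # a model rebuilt from the file reproduces the strand paths and shares
  model2 <- build_jaw_model(attachments = tab)
  expect_equal(length(model2$strands), length(model$strands))
  i <- which(model$strand_table$muscle == "medial_pterygoid" &
               model$strand_table$side == "right")[1]
  j <- which(model2$strand_table$muscle == "medial_pterygoid" &
               model2$strand_table$side == "right")[1]
  expect_equal(model2$strands[[j]]$path, model$strands[[i]]$path,
               ignore_attr = TRUE)
  expect_equal(model2$strands[[j]]$max_force_share,
               model$strands[[i]]$max_force_share)
})

test_that("attachment reader rejects malformed rows, naming the row", {
  model <- default_model()
  path <- withr::local_tempfile(fileext = ".csv")
  write_attachments(model, path)
  good <- utils::read.csv(path, stringsAsFactors = FALSE)

  bad <- good; bad$muscle[5] <- "mystery_muscle"
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_attachments(f), "mystery_muscle")
  expect_error(read_attachments(f), "row 5")

  bad <- good; bad$frame[9] <- ""
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_attachments(f), "frame")

  bad <- good; bad$x[3] <- "not-a-number"
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_attachments(f), "non-numeric")

  bad <- good[good$muscle != "superficial_masseter", ]
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(build_jaw_model(attachments = f), "superficial_masseter")
})

test_that("digastric strands may carry via points in loaded files", {
  # minimal well-formed table: one 3-point strand per muscle + digastric
  rows <- function(muscle, which_side) {
    sgn <- if (which_side == "left") -1 else 1
    tibble::tibble(
      muscle = muscle, side = which_side, strand = 1,
      role = c("origin", "via", "insertion"),
      frame = c("cranium", "cranium", "mandible"),
      x = c(0, 5, 10), y = sgn * c(-10, -8, -6),
      z = c(5, 0, -5), ordinal = 1:3)
  }
  full <- dplyr::bind_rows(purrr::map(
    c(jaw_closer_parts(), "digastric"),
    function(m) dplyr::bind_rows(rows(m, "right"), rows(m, "left"))))
  model <- build_jaw_model(attachments = full)
  dig <- model$strands[[which(model$strand_table$muscle == "digastric" &
                                model$strand_table$side == "right")[1]]]
  expect_equal(nrow(dig$path), 3)
  expect_equal(dig$frames[2], "cranium")
})
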