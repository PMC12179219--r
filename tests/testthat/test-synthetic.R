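test_that("layer textures are deterministic, bounded, and validated", {
  a <- gen_layer_texture("epithelium", 64, seed = 7)
  b <- gen_layer_texture("epithelium", 64, seed = 7)
  expect_identical(a$pixels, b$pixels)

  small <- gen_layer_texture("endothelium", 32, seed = 0)
  expect_equal(dim(small$pixels), c(32L, 32L))
  expect_true(all(small$pixels >= 0 & small$pixels <= 255))

  expect_error(gen_layer_texture("epithelium", 16, seed = 1), ">= 32")
  expect_error(gen_layer_texture("bowman", 64, seed = 1), "unknown layer")
  expect_error(gen_layer_texture("stroma", 64, seed = -1), "integer")
})

test_that("nerve plexus textures are edge-denser than stromal textures", {
  # ridge/edge-pixel fraction with the fixed gradient threshold; the texture
  # recipes must keep this ordering for essentially every seed
  wins <- vapply(1:30, function(s) {
    edge_fraction(gen_layer_texture("nerve_plexus", 128, s)) >
      edge_fraction(gen_layer_texture("stroma", 128, s))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("the four layer classes are separable by trivial statistics", {
  # nearest class-mean on an 8-bin intensity histogram + edge fraction must
  # reach 90% four-class accuracy on 200 generated normals
  feats <- list(); labs <- character(0)
  for (l in c("epithelium", "nerve_plexus", "stroma", "endothelium")) {
    for (s in 1:50) {
      img <- gen_layer_texture(l, 64, 1000 + s)
      h <- hist(img$pixels, breaks = seq(0, 256, 32), plot = FALSE)$counts
      feats[[length(feats) + 1]] <- c(h / sum(h), edge_fraction(img))
      labs <- c(labs, l)
    }
  }
  x <- do.call(rbind, feats)
  mu <- sapply(split(as.data.frame(x), labs), colMeans)
  pred <- colnames(mu)[apply(x, 1, function(r) which.min(colSums((mu - r)^2)))]
  expect_gte(mean(pred == labs), 0.90)
})

test_that("lesion injection changes exactly the masked pixels, at the right area", {
  img <- gen_layer_texture("stroma", 64, 1)
  for (kind in c("bright_blob", "filament_tangle", "texture_dropout", "dark_patch")) {
    for (sev in c(0.02, 0.1, 0.3)) {
      out <- inject_anomaly(img, anomaly_spec(kind, sev, seed = 3))
      changed <- out$image$pixels != img$pixels
      expect_identical(unname(which(changed)), unname(which(out$mask)),
                       info = sprintf("%s sev %.2f", kind, sev))
      frac <- mean(out$mask)
      expect_gte(frac, 0.5 * sev)
      expect_lte(frac, 2 * sev)
      expect_identical(out$image$label, "anomalous")
    }
  }
  # determinism: same image and spec twice
  s <- anomaly_spec("bright_blob", 0.1, seed = 11)
  expect_identical(inject_anomaly(img, s), inject_anomaly(img, s))
  expect_error(anomaly_spec("bright_blob", 0.6, 1), "severity")
  expect_error(anomaly_spec("bright_blob", 0, 1), "severity")
})

test_that("synthetic cohorts are organized by eye with exact anomaly counts", {
  co <- build_synthetic_cohort(10, 4, anomalous_eye_fraction = 0, size = 64, seed = 5)
  expect_equal(nrow(co$manifest), 40L)
  expect_true(all(co$manifest$label == "normal"))
  expect_length(co$masks, 0L)

  co3 <- build_synthetic_cohort(10, 4, anomalous_eye_fraction = 0.3, size = 64, seed = 5)
  anom_eyes <- unique(co3$manifest$eye_id[co3$manifest$label == "anomalous"])
  expect_length(anom_eyes, 3L)  # floor(0.3 * 10)
  # eyes are wholly one label
  tab <- table(co3$manifest$eye_id, co3$manifest$label)
  expect_true(all(rowSums(tab > 0) == 1))
  # every anomalous image has a non-empty mask; normals have none
  anom_paths <- co3$manifest$path[co3$manifest$label == "anomalous"]
  expect_setequal(names(co3$masks), anom_paths)
  expect_true(all(vapply(co3$masks, sum, numeric(1)) >= 1))
  # normal eyes draw from all four layer classes
  norm <- co3$manifest[co3$manifest$label == "normal", ]
  expect_setequal(unique(norm$layer_class),
                  c("epithelium", "nerve_plexus", "stroma", "endothelium"))
  # byte-identical manifests on repeat
  co3b <- build_synthetic_cohort(10, 4, anomalous_eye_fraction = 0.3, size = 64, seed = 5)
  expect_identical(co3$manifest, co3b$manifest)
  expect_error(build_synthetic_cohort(10, 4, anomalous_eye_fraction = 1.2), "fraction")
})

test_that("cohorts round-trip through disk as PNGs and manifest CSV", {
  dir <- withr::local_tempdir()
  co <- build_synthetic_cohort(4, 2, anomalous_eye_fraction = 0.5, size = 64, seed = 2)
  mpath <- write_cohort(co, dir)
  man <- read_manifest(mpath)
  expect_equal(man, co$manifest)
  p <- man$path[1]
  rgb <- load_image(file.path(dir, p))
  expect_equal(rgb[, , 1], matrix(as.numeric(co$images[[p]]$pixels), 64, 64))
})
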