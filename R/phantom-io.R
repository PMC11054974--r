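#' @include phantom-generate.R
NULL

#' Write a synthetic dataset to disk
#'
#' Streams the dataset described by a manifest into a directory tree:
#' `images/<fruit>_r<rot>.png` (8-bit RGB), `spectra/<fruit>_r<rot>.csv`
#' (columns `wavelength_nm`, `raw`, `white_ref`, `dark_ref`),
#' `haptic/<fruit>_r<rot>.csv` (columns `time_s`, `pressure_kpa`), and
#' `manifest.json` at the root (records, seed, class counts, and the
#' fruit-level quality attributes). Content is fully determined by the
#' manifest seed; a round-trip read reproduces arrays within 8-bit /
#' float-text precision.
#'
#' @param manifest a [PhantomManifest-class].
#' @param outDir output directory.
#' @param config generator configuration.
#' @param overwrite refuse to write into an existing dataset unless TRUE.
#' @return `outDir`, invisibly.
#' @export
writeDataset <- function(manifest, outDir, config = phantomDefaults(),
                         overwrite = FALSE) {
  manifestPath <- file.path(outDir, "manifest.json")
  if (file.exists(manifestPath) && !overwrite)
    stop("dataset already exists at ", outDir,
         " (use overwrite = TRUE to replace it)")
  for (d in c("", "images", "spectra", "haptic"))
    dir.create(file.path(outDir, d), recursive = TRUE, showWarnings = FALSE)
  fruits <- unique(manifest@records[, c("fruit_id", "label")])
  rotations <- seq_len(manifest@nRotations) - 1L
  fruits$ssc <- NA_real_
  fruits$firmness <- NA_real_
  for (i in seq_len(nrow(fruits))) {
    fl <- fruitLevelDraws(manifest@seed, i, fruits$label[i], config)
    fruits$ssc[i] <- fl$quality$ssc[1]
    fruits$firmness[i] <- fl$quality$firmness[1]
    for (rot in rotations) {
      s <- generateSample(fruits$label[i], fruits$fruit_id[i], rot, config,
                          seed = recordSeed(manifest@seed, i, rot, 3L),
                          quality = fl$quality, plateau = fl$plateau,
                          redFrac = fl$redFrac)
      stem <- sprintf("%s_r%d", fruits$fruit_id[i], rot)
      png::writePNG(s@image / 255,
                    file.path(outDir, "images", paste0(stem, ".png")))
      utils::write.csv(
        data.frame(wavelength_nm = wavelengths(s@spectrum),
                   raw = rawSignal(s@spectrum),
                   white_ref = whiteReference(s@spectrum),
                   dark_ref = darkReference(s@spectrum)),
        file.path(outDir, "spectra", paste0(stem, ".csv")),
        row.names = FALSE)
      n <- length(pressure(s@haptic))
      utils::write.csv(
        data.frame(time_s = (seq_len(n) - 1) / sampleRate(s@haptic),
                   pressure_kpa = pressure(s@haptic)),
        file.path(outDir, "haptic", paste0(stem, ".csv")),
        row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(seed = manifest@seed,
         n_rotations = manifest@nRotations,
         class_counts = as.list(manifest@classCounts),
         fruits = fruits,
         records = manifest@records),
    manifestPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Read a dataset manifest back from disk
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return List with elements `manifest` (a [PhantomManifest-class]),
#'   `fruits` (fruit-level table incl. quality attributes), and `dir`.
#' @export
readDataset <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path))
    stop("no manifest.json under ", dir)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- unlist(j$class_counts)
  counts <- integer(length(allLabels()))
  names(counts) <- allLabels()
  counts[names(cc)] <- as.integer(cc)
  manifest <- new("PhantomManifest",
                  records = as.data.frame(j$records),
                  seed = as.numeric(j$seed),
                  classCounts = counts,
                  nRotations = as.integer(j$n_rotations))
  list(manifest = manifest, fruits = as.data.frame(j$fruits), dir = dir)
}

#' Load one acquisition triplet from a written dataset
#'
#' @param dataset result of [readDataset()].
#' @param fruitId,rotation which acquisition to load.
#' @return A [TomatoSample-class] (8-bit image values restored exactly;
#'   spectra and traces at text precision).
#' @export
readSample <- function(dataset, fruitId, rotation = 0L) {
  fr <- dataset$fruits[dataset$fruits$fruit_id == fruitId, , drop = FALSE]
  if (!nrow(fr))
    stop("unknown fruit id: ", fruitId)
  stem <- sprintf("%s_r%d", fruitId, rotation)
  img <- png::readPNG(file.path(dataset$dir, "images",
                                paste0(stem, ".png"))) * 255
  img <- round(img)
  sp <- utils::read.csv(file.path(dataset$dir, "spectra",
                                  paste0(stem, ".csv")))
  tr <- utils::read.csv(file.path(dataset$dir, "haptic",
                                  paste0(stem, ".csv")))
  rate <- 1 / stats::median(diff(tr$time_s))
  new("TomatoSample", fruitId = fruitId, rotation = as.integer(rotation),
      label = fr$label[1], image = img,
      spectrum = Spectrum(sp$wavelength_nm, sp$raw, sp$white_ref,
                          sp$dark_ref),
      haptic = HapticTrace(tr$pressure_kpa, rate),
      ssc = fr$ssc[1], firmness = fr$firmness[1])
}
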