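# End-to-end pipeline: generate -> preprocess -> unmix -> SNR/SII -> score,
# writing plain-text artifacts plus a manifest with content hashes.  All
# randomness derives from the single config seed, so a fixed config yields
# byte-identical outputs.

#' Default pipeline configuration
#'
#' @return Named list of all recognized configuration keys with defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    protocols = c("E_24", "T_12", "HF_8"),
    quality = c(E_24 = 0.9, T_12 = 0.7, HF_8 = 0.4),
    grid_shape = c(8, 8),
    k = 2,
    n_batches = 2,
    n_observers = 2,
    disagreement_sd = 0.1,
    noise_sd = 2,
    cosmic_ray_rate = 0.05,
    snip_iterations = 400,
    despike_z = 8
  )
}

#' @noRd
load_config <- function(config, out_dir = NULL) {
  base <- default_config()
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::fromJSON(config)
    if (!is.null(config$quality)) config$quality <- unlist(config$quality)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path", call. = FALSE)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  base[names(config)] <- config
  if (!is.null(out_dir)) base$out_dir <- out_dir
  if (is.null(base$out_dir)) stop("config must set out_dir", call. = FALSE)
  for (p in base$protocols) parse_protocol(p)
  base
}

#' @noRd
write_csv_plain <- function(df, path) {
  body <- character(0)
  if (nrow(df) > 0L) {
    cols <- vapply(df, function(col) {
      if (is.double(col)) fmt_num(col) else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1)
    body <- apply(cols, 1, paste, collapse = ",")
  }
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c(paste(names(df), collapse = ","), body), con, sep = "\n")
  invisible(path)
}

#' Run the full decalcifier-comparison pipeline on synthetic data
#'
#' Generates one bone-marrow and one compact-bone scan per protocol plus
#' score tables and acquisition settings (all seeded), preprocesses the
#' scans, unmixes the marrow scans with N-FINDR, computes SNR and SII
#' statistics, aggregates observer scores into modality totals and final
#' cross-modality scores, and writes every artifact as plain text together
#' with a `manifest.json` listing file MD5 hashes.
#'
#' @param config Named list or path to a JSON file; see [default_config()]
#'   for the recognized keys.  Unknown keys are rejected.  A demo config is
#'   shipped at `system.file("extdata", "demo-config.json", package = "decalQC")`.
#' @param out_dir Output directory; overrides the config's `out_dir` and is
#'   required if the config does not set one.
#' @return Invisibly, the manifest as a list (`config`, `files` with
#'   per-file MD5 hashes, and `final_scores`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_config(config, out_dir = out_dir)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  quality <- cfg$quality
  if (length(quality) == 1L && is.null(names(quality)))
    quality <- stats::setNames(rep(quality, length(cfg$protocols)), cfg$protocols)

  files <- character(0)
  put <- function(name) { files <<- c(files, name); file.path(cfg$out_dir, name) }

  # --- stage 1: synthetic inputs -------------------------------------------
  silicon <- make_silicon_spectrum(true_peak = 520.8, noise_sd = 1,
                                   seed = seed + 11L)
  tables <- lapply(c("HE", "fluorescence", "raman"), function(mod) {
    make_score_fixture(cfg$protocols, quality = quality,
                       n_batches = cfg$n_batches,
                       n_observers = cfg$n_observers,
                       disagreement_sd = cfg$disagreement_sd,
                       modality = mod, seed = seed + 101L + match(mod, c("HE", "fluorescence", "raman")))
  })
  scores <- do.call(rbind, tables)
  class(scores) <- c("score_table", "data.frame")
  write_score_table(scores, put("score_table.csv"))
  acq <- make_acquisition_fixture(cfg$protocols, quality = quality,
                                  n_batches = cfg$n_batches,
                                  seed = seed + 301L)
  write_acquisition_table(acq, put("acquisition.csv"))

  marrow <- list(); compact <- list()
  for (i in seq_along(cfg$protocols)) {
    p <- cfg$protocols[i]
    marrow[[p]] <- make_scan(cfg$grid_shape, roi = "bone_marrow", protocol = p,
                             k = cfg$k, noise_sd = cfg$noise_sd / quality[[p]],
                             cosmic_ray_rate = cfg$cosmic_ray_rate,
                             seed = seed + 401L + i)
    compact[[p]] <- make_scan(c(4, 4), roi = "compact_bone", protocol = p,
                              k = 1, noise_sd = cfg$noise_sd / quality[[p]],
                              cosmic_ray_rate = cfg$cosmic_ray_rate,
                              seed = seed + 501L + i)
  }

  # --- stage 2-4: preprocessing, unmixing, quality statistics --------------
  snr_rows <- list(); em_rows <- list(); med_rows <- list()
  for (p in cfg$protocols) {
    # SNR before truncation (the silent region must still be present)
    snr_cb <- scan_snr(compact[[p]])
    snr_bm <- scan_snr(marrow[[p]])
    snr_rows[[p]] <- data.frame(protocol = p,
                                tissue = c("compact_bone", "bone_marrow"),
                                snr = c(snr_cb$snr, snr_bm$snr))
    med <- preprocess_compact(compact[[p]], silicon,
                              snip_iterations = cfg$snip_iterations,
                              despike_z = cfg$despike_z)$median
    med_rows[[p]] <- data.frame(protocol = p, wavenumber = med$wavenumber,
                                intensity = med$intensity)
    pre <- preprocess_marrow(marrow[[p]], silicon, despike_z = cfg$despike_z)
    em <- nfindr(pre$scan, k = cfg$k, seed = seed + 601L)
    ab <- estimate_abundances(pre$scan, em)
    nuc <- suggest_nuclei_channel(em)
    img <- false_color_image(ab, nuc)
    em_rows[[p]] <- data.frame(protocol = p,
                               endmember = rep(seq_len(em$k),
                                               each = length(em$wavenumber)),
                               wavenumber = rep(em$wavenumber, em$k),
                               intensity = as.vector(t(em$spectra)))
    write_csv_plain(as.data.frame(img), put(paste0("false_color_", p, ".csv")))
  }
  write_csv_plain(do.call(rbind, med_rows), put("median_spectra.csv"))
  write_csv_plain(do.call(rbind, em_rows), put("endmembers.csv"))
  snr_df <- do.call(rbind, snr_rows)
  rownames(snr_df) <- NULL
  write_csv_plain(snr_df, put("snr.csv"))

  # --- stage 5: scoring ----------------------------------------------------
  set2_fluo <- acquisition_to_set2_scores(acq)
  snr_scores <- do.call(rbind, lapply(c("compact_bone", "bone_marrow"), function(tis) {
    sel <- snr_df$tissue == tis
    data.frame(protocol = snr_df$protocol[sel], tissue = tis,
               score = as.integer(snr_to_score(snr_df$snr[sel], tissue = tis)))
  }))
  write_csv_plain(snr_scores, put("snr_scores.csv"))

  final_rows <- list()
  for (p in cfg$protocols) {
    he <- aggregate_qualitative(scores, "HE", p)$normalized_score
    f1 <- aggregate_qualitative(scores, "fluorescence", p)$normalized_score
    f2 <- set2_fluo$set2_score[set2_fluo$protocol == p]
    r1 <- aggregate_qualitative(scores, "raman", p)$normalized_score
    r2 <- mean(snr_scores$score[snr_scores$protocol == p]) / 2
    fs <- final_score(he = he, fluorescence = modality_total(f1, f2),
                      raman = modality_total(r1, r2), protocol = p)
    final_rows[[p]] <- data.frame(protocol = p, he = he,
                                  fluorescence = modality_total(f1, f2),
                                  raman = modality_total(r1, r2),
                                  final = fs$mean_score,
                                  sd = fs$sd_across_modalities)
  }
  final_df <- do.call(rbind, final_rows)
  rownames(final_df) <- NULL
  write_csv_plain(final_df, put("final_scores.csv"))

  disagreements <- do.call(rbind, lapply(c("HE", "fluorescence", "raman"),
                                         function(m) {
    fl <- flag_disagreements(scores, m)
    if (nrow(fl)) cbind(modality = m, fl) else NULL
  }))
  if (is.null(disagreements))
    disagreements <- data.frame(modality = character(0), protocol = character(0),
                                batch = integer(0), max_difference = numeric(0))
  write_csv_plain(disagreements, put("disagreements.csv"))

  # --- manifest ------------------------------------------------------------
  hashes <- as.list(tools::md5sum(file.path(cfg$out_dir, sort(files))))
  names(hashes) <- sort(files)
  manifest <- list(config = cfg[setdiff(names(cfg), "out_dir")],
                   files = hashes,
                   final_scores = stats::setNames(final_df$final,
                                                  final_df$protocol))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
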