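#' Assemble a structured assessment report
#'
#' Builds the four-section report document: patient details, prostate
#' size and PSA density, clinically significant lesion candidates (sorted
#' by descending probability, labelled LESION 1..n), and a findings
#' summary paragraph populated from the other sections. Numeric fields
#' are rounded at build time so renders are reproducible: lengths and
#' volumes to 1 decimal place, PSA density to 3, probabilities to whole
#' percent, minimum ADC to 3 significant digits.
#'
#' @param patient A [patient_record()].
#' @param measurements A [prostate_measurements()].
#' @param lesions List of `lesion_candidate` objects (any order; sorted
#'   internally).
#' @param config_hash Provenance string identifying the configuration.
#' @param timestamp Report creation time (string); defaults to the
#'   current UTC time, fixed in the document thereafter.
#' @return An object of class `report_document`.
#' @export
build_report <- function(patient, measurements, lesions = list(),
                         config_hash = "unconfigured",
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC")) {
  stopifnot(inherits(patient, "patient_record"),
            inherits(measurements, "prostate_measurements"))
  lesions <- rank_lesions(lesions)
  les_rows <- lapply(seq_along(lesions), function(i) {
    l <- lesions[[i]]
    list(label = sprintf("LESION %d", i),
         probability_pct = round(100 * l$probability),
         centroid_slice = l$centroid_slice,
         centroid_zone = l$centroid_zone,
         centroid_region = l$centroid_region,
         volume_cm3 = round(l$volume_cm3, 1),
         min_adc_mm2s = signif(l$min_adc, 3),
         extracapsular = isTRUE(l$extracapsular))
  })
  psad_avail <- !is.na(measurements$psa_density)
  size_sec <- list(
    transverse_cm = round(measurements$transverse_cm, 1),
    anterior_posterior_cm = round(measurements$anterior_posterior_cm, 1),
    cranio_caudal_cm = round(measurements$cranio_caudal_cm, 1),
    prostate_volume_cm3 = round(measurements$wp_volume_cm3, 1),
    peripheral_zone_volume_cm3 = round(measurements$pz_volume_cm3, 1),
    central_gland_volume_cm3 = round(measurements$cg_volume_cm3, 1),
    psa_density = if (psad_avail) round(measurements$psa_density, 3)
                  else "unavailable")
  summary_txt <- findings_summary(patient, size_sec, les_rows, psad_avail)
  structure(
    list(patient = list(
           name = patient$name,
           hospital_number = patient$hospital_number,
           date_of_birth = format(patient$date_of_birth, "%Y-%m-%d"),
           scan_date = format(patient$scan_date, "%Y-%m-%d"),
           age_years = patient$age,
           psa_ng_ml = patient$psa),
         sections = list(
           patient_details = TRUE,
           prostate_size_and_psa_density = size_sec,
           lesion_candidates = les_rows,
           findings_summary = summary_txt),
         provenance = list(
           software = paste0("prostcad ",
                             as.character(utils::packageVersion("prostcad"))),
           config_hash = config_hash,
           created = timestamp)),
    class = "report_document")
}

findings_summary <- function(patient, size_sec, les_rows, psad_avail) {
  vol_txt <- sprintf(
    "The prostate measures %.1f x %.1f x %.1f cm (transverse x anterior-posterior x cranio-caudal) with a volume of %.1f cm3.",
    size_sec$transverse_cm, size_sec$anterior_posterior_cm,
    size_sec$cranio_caudal_cm, size_sec$prostate_volume_cm3)
  psad_txt <- if (psad_avail)
    sprintf(" PSA is %.2f ng/mL giving a PSA density of %.3f ng/mL2.",
            patient$psa_ng_ml, size_sec$psa_density)
  else " PSA was not provided; PSA density is unavailable."
  les_txt <- if (length(les_rows) == 0L)
    " No clinically significant lesion candidates were detected above the operating threshold."
  else {
    top <- les_rows[[1]]
    sprintf(
      " %d clinically significant lesion candidate%s detected; the most suspicious (%s, probability %d%%) lies in the %s %s with a volume of %.1f cm3 and a minimum ADC of %s mm2/s.",
      length(les_rows), if (length(les_rows) == 1L) " was" else "s were",
      top$label, top$probability_pct, top$centroid_region,
      top$centroid_zone, top$volume_cm3,
      format(top$min_adc_mm2s, scientific = TRUE))
  }
  paste0(vol_txt, psad_txt, les_txt)
}

#' Render a report document to canonical JSON
#'
#' Key order is fixed by construction and all numeric fields were rounded
#' at build time, so semantically equal documents render byte-identically
#' and the output round-trips through [parse_report_json()].
#'
#' @param doc A `report_document`.
#' @return A JSON string (UTF-8).
#' @export
render_json <- function(doc) {
  stopifnot(inherits(doc, "report_document"))
  as.character(jsonlite::toJSON(unclass(doc), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE))
}

#' Parse a rendered report back into a document
#'
#' @param json JSON string produced by [render_json()].
#' @return A `report_document` equal to the one rendered.
#' @export
parse_report_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  structure(x, class = "report_document")
}

#' Render a report document to static HTML
#'
#' Writes a self-contained HTML file with the four report sections in
#' order: Patient Details; Prostate Size and PSA Density; Clinically
#' Significant Lesion Candidates; Findings Summary. Optional pre-rendered
#' overlay images (PNG paths) are embedded per lesion; an overlay whose
#' file is missing is skipped with a warning.
#'
#' @param doc A `report_document`.
#' @param path Output HTML path.
#' @param overlays Optional character vector of image paths, one per
#'   lesion row.
#' @return `path`, invisibly.
#' @export
render_html <- function(doc, path, overlays = NULL) {
  stopifnot(inherits(doc, "report_document"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  p <- doc$patient
  s <- doc$sections$prostate_size_and_psa_density
  rows <- doc$sections$lesion_candidates
  les_html <- if (length(rows) == 0L)
    "<p>No clinically significant lesion candidates above threshold.</p>"
  else {
    hdr <- "<tr><th>Lesion</th><th>Probability of CSPCa (%)</th><th>Centroid Slice</th><th>Centroid Zone</th><th>Centroid Region</th><th>Volume (cm3)</th><th>Min ADC (mm2/s)</th><th>Extra-Capsular?</th></tr>"
    body <- vapply(seq_along(rows), function(i) {
      r <- rows[[i]]
      img <- ""
      if (!is.null(overlays) && i <= length(overlays) &&
          !is.na(overlays[i])) {
        if (file.exists(overlays[i]))
          img <- sprintf("<br/><img src=\"%s\" alt=\"%s overlay\"/>",
                         esc(overlays[i]), esc(r$label))
        else warning(sprintf("overlay for %s not found; skipped", r$label),
                     call. = FALSE)
      }
      sprintf(
        "<tr><td>%s%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
        esc(r$label), img, r$probability_pct, r$centroid_slice,
        esc(r$centroid_zone), esc(r$centroid_region), r$volume_cm3,
        format(r$min_adc_mm2s, scientific = TRUE),
        tolower(as.character(r$extracapsular)))
    }, character(1))
    paste0("<table border=\"1\">", hdr, paste(body, collapse = ""),
           "</table>")
  }
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
    "<title>Prostate MRI Assessment Report</title></head><body>\n",
    "<h1>Prostate MRI Assessment Report</h1>\n",
    "<h2>Patient Details</h2>\n<table border=\"1\">",
    sprintf("<tr><td>Patient Name</td><td>%s</td></tr>", esc(p$name)),
    sprintf("<tr><td>Hospital Number</td><td>%s</td></tr>",
            esc(p$hospital_number)),
    sprintf("<tr><td>Date of Birth</td><td>%s</td></tr>",
            esc(p$date_of_birth)),
    sprintf("<tr><td>Scan Date</td><td>%s</td></tr>", esc(p$scan_date)),
    sprintf("<tr><td>Age (years)</td><td>%s</td></tr>", p$age_years),
    sprintf("<tr><td>PSA (ng/mL)</td><td>%s</td></tr>", p$psa_ng_ml),
    "</table>\n",
    "<h2>Prostate Size and PSA Density</h2>\n<table border=\"1\">",
    sprintf("<tr><td>Transverse (cm)</td><td>%s</td></tr>",
            s$transverse_cm),
    sprintf("<tr><td>Anterior-Posterior (cm)</td><td>%s</td></tr>",
            s$anterior_posterior_cm),
    sprintf("<tr><td>Cranio-Caudal (cm)</td><td>%s</td></tr>",
            s$cranio_caudal_cm),
    sprintf("<tr><td>Prostate Volume (cm3)</td><td>%s</td></tr>",
            s$prostate_volume_cm3),
    sprintf("<tr><td>Peripheral Zone Volume (cm3)</td><td>%s</td></tr>",
            s$peripheral_zone_volume_cm3),
    sprintf("<tr><td>Central Gland Volume (cm3)</td><td>%s</td></tr>",
            s$central_gland_volume_cm3),
    sprintf("<tr><td>PSA Density (ng/mL2)</td><td>%s</td></tr>",
            s$psa_density),
    "</table>\n",
    "<h2>Clinically Significant Lesion Candidates</h2>\n", les_html, "\n",
    "<h2>Findings Summary</h2>\n<p>",
    esc(doc$sections$findings_summary), "</p>\n",
    sprintf("<hr/><small>%s | config %s | %s</small>\n",
            esc(doc$provenance$software), esc(doc$provenance$config_hash),
            esc(doc$provenance$created)),
    "</body></html>\n")
  writeLines(html, path)
  invisible(path)
}
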