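# Static report assembly: a self-contained JSON + HTML snapshot of the
# pipeline's stage outputs (cohort summary, density profiles, test
# results, junction-structure fractions, reciprocal balance counts,
# motif enrichment). Plumbing only: every number is passed through from
# a stage output, never recomputed here.

.load_stage <- function(x, name) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      .stop_format("report stage '%s': file not found: %s", name, x)
    }
    ext <- tolower(tools::file_ext(x))
    x <- switch(ext,
      json = jsonlite::read_json(x, simplifyVector = TRUE),
      tsv = utils::read.table(x, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, comment.char = "#"),
      .stop_format("report stage '%s': unsupported file type '.%s'", name, ext)
    )
  }
  x
}

.svg_barchart <- function(counts, width = 560, height = 120, fill = "#4878a8") {
  n <- length(counts)
  if (n == 0L || max(counts) == 0) return("<p>(no data)</p>")
  bw <- width / n
  bars <- vapply(seq_len(n), function(i) {
    h <- height * counts[i] / max(counts)
    sprintf('<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="%s"/>',
            (i - 1) * bw, height - h, bw * 0.9, h, fill)
  }, character(1L))
  sprintf('<svg width="%d" height="%d" role="img">%s</svg>',
          width, height, paste(bars, collapse = ""))
}

.html_table <- function(df) {
  if (is.null(df) || !nrow(df)) return("<p>(empty)</p>")
  head <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""),
                 "</tr>")
  body <- apply(df, 1L, function(r) {
    paste0("<tr>", paste0("<td>", as.character(r), "</td>", collapse = ""),
           "</tr>")
  })
  paste0("<table>", head, paste(body, collapse = ""), "</table>")
}

#' Assemble a static breakpoint report
#'
#' Collects stage outputs into a deterministic, self-contained report:
#' `report.json` (machine-readable; byte-identical across runs on
#' identical inputs) and `report.html` (renders without network
#' access). Sections whose stage output is missing are marked absent
#' rather than failing the build.
#'
#' @param stage_outputs named list; recognized names are
#'   `cohort_summary`, `profiles` (a named list of
#'   [density_profile()] frames), `tests` (a named list of
#'   `dist_test_result` objects or equivalent lists), `junctions` (a
#'   [classify_cohort()] result), `reciprocal` (a
#'   [cohort_reciprocal_report()] result), `enrichment` (an
#'   [enrichment_scan()] frame). Each element may also be a path to a
#'   `.json` or `.tsv` file written by the stage.
#' @param out_dir output directory (created if needed).
#' @param provenance named list recorded verbatim (seeds, config hash,
#'   versions); the package version is always added.
#' @return paths of the written files, invisibly.
#' @export
build_report <- function(stage_outputs, out_dir, provenance = list()) {
  stopifnot(is.list(stage_outputs))
  known <- c("cohort_summary", "profiles", "tests", "junctions",
             "reciprocal", "enrichment")
  unknown <- setdiff(names(stage_outputs), known)
  if (length(unknown)) {
    .stop_format("unknown report stage(s): %s", paste(unknown, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sections <- stats::setNames(vector("list", length(known)), known)
  for (nm in known) {
    x <- stage_outputs[[nm]]
    sections[[nm]] <- if (is.null(x)) {
      list(present = FALSE)
    } else {
      list(present = TRUE, data = .load_stage(x, nm))
    }
  }
  if (isTRUE(sections$tests$present)) {
    sections$tests$data <- lapply(sections$tests$data, function(t) {
      if (inherits(t, "dist_test_result")) unclass(t) else t
    })
  }
  if (isTRUE(sections$junctions$present) &&
      is.list(sections$junctions$data) &&
      !is.null(sections$junctions$data$calls)) {
    # the per-call table can be large; the report keeps the summaries
    d <- sections$junctions$data
    sections$junctions$data <- list(
      fractions = as.list(d$fractions),
      mh_summary = d$mh_summary, ins_summary = d$ins_summary,
      n_classifiable = d$n_classifiable,
      n_unclassifiable = if (is.null(d$unclassifiable)) 0L
                         else nrow(d$unclassifiable))
  }
  provenance$package_version <- as.character(utils::packageVersion("breakfusion"))
  report <- list(sections = sections, provenance = provenance)

  json_path <- file.path(out_dir, "report.json")
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, null = "null", na = "null")
  writeLines(json, json_path)

  html_path <- file.path(out_dir, "report.html")
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Breakpoint report</title>",
    "<style>body{font-family:sans-serif;max-width:60em;margin:2em auto}",
    "table{border-collapse:collapse}td,th{border:1px solid #999;",
    "padding:2px 8px;font-size:0.9em}h2{border-bottom:1px solid #ccc}",
    "</style></head><body>",
    "<h1>Translocation breakpoint report</h1>"
  )
  add <- function(...) parts <<- c(parts, ...)
  section_html <- function(title, s, render) {
    add(sprintf("<h2>%s</h2>", title))
    if (!isTRUE(s$present)) add("<p><em>section absent</em></p>") else render(s$data)
  }
  section_html("Cohort summary", sections$cohort_summary, function(d) {
    add(.html_table(as.data.frame(lapply(d, function(v)
      paste(format(v), collapse = ", ")), check.names = FALSE)))
  })
  section_html("Breakpoint density profiles", sections$profiles, function(d) {
    for (nm in names(d)) {
      add(sprintf("<h3>%s</h3>", nm), .svg_barchart(d[[nm]]$count))
    }
  })
  section_html("Distribution tests", sections$tests, function(d) {
    df <- do.call(rbind, lapply(names(d), function(nm) {
      t <- d[[nm]]
      data.frame(test = nm, method = t$method,
                 statistic = signif(t$statistic, 5),
                 p_value = signif(t$p_value, 5))
    }))
    add(.html_table(df))
  })
  section_html("Junction primary structure", sections$junctions, function(d) {
    fr <- unlist(d$fractions)
    add(.html_table(data.frame(mechanism = names(fr),
                               fraction = signif(fr, 4))))
    add(sprintf("<p>classifiable: %d; unclassifiable: %d</p>",
                d$n_classifiable, d$n_unclassifiable))
  })
  section_html("Reciprocal balance", sections$reciprocal, function(d) {
    scalars <- d[vapply(d, function(v) length(v) == 1L, logical(1L))]
    add(.html_table(data.frame(quantity = names(scalars),
                               value = signif(unlist(scalars), 6))))
  })
  section_html("Motif proximity", sections$enrichment, function(d) {
    add(.html_table(as.data.frame(d)))
  })
  add(sprintf("<h2>Provenance</h2><pre>%s</pre>",
              paste(sprintf("%s: %s", names(provenance),
                            vapply(provenance, function(v)
                              paste(format(v), collapse = " "),
                              character(1L))),
                    collapse = "\n")),
      "</body></html>")
  writeLines(paste(parts, collapse = "\n"), html_path)
  invisible(c(json = json_path, html = html_path))
}
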