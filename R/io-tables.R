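#' @include trajectory-methods.R
NULL

#' Read and write NOE restraint tables
#'
#' Delimited text with a one-line header:
#' \code{i,atom_i,j,atom_j,upper_bound_A}.
#'
#' @param path file path.
#' @param restraints list of \linkS4class{NOERestraint} (writer).
#' @return Reader: list of \linkS4class{NOERestraint}; writer: the path,
#'   invisibly.
#' @export
readRestraints <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("i", "atom_i", "j", "atom_j", "upper_bound_A")
  if (!all(need %in% names(tab)))
    stop("restraint table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(tab)), function(k)
    NOERestraint(tab$i[k], tab$atom_i[k], tab$j[k], tab$atom_j[k],
                 tab$upper_bound_A[k]))
}

#' @rdname readRestraints
#' @export
writeRestraints <- function(restraints, path) {
  tab <- do.call(rbind, lapply(restraints, function(r)
    data.frame(i = r@resI, atom_i = r@atomI, j = r@resJ, atom_j = r@atomJ,
               upper_bound_A = r@upper)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write ITC isotherm files
#'
#' Delimited text: comment header lines \code{#key value} carrying the
#' cell/syringe concentrations, cell volume, temperature and outer-leaflet
#' fraction, then CSV rows \code{injection_volume_ul,heat_uJ}.
#'
#' @param path file path.
#' @param exp An \linkS4class{ITCExperiment} (writer).
#' @return Reader: an \linkS4class{ITCExperiment}; writer: the path,
#'   invisibly.
#' @export
readIsotherm <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- list()
  for (h in hdr) {
    p <- strsplit(sub("^#", "", h), " +")[[1]]
    kv[[p[1]]] <- as.numeric(p[2])
  }
  tab <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  ITCExperiment(cellConc = kv$cell_conc_uM, syringeConc = kv$syringe_conc_mM,
                injectionVolumes = tab$injection_volume_ul,
                heats = tab$heat_uJ,
                cellVolume = kv$cell_volume_ul %||% 170,
                temperature = kv$temperature_K %||% 298.15,
                outerFraction = kv$outer_fraction %||% 0.5)
}

#' @rdname readIsotherm
#' @export
writeIsotherm <- function(exp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#cell_conc_uM %.10g", exp@cellConc),
               sprintf("#syringe_conc_mM %.10g", exp@syringeConc),
               sprintf("#cell_volume_ul %.10g", exp@cellVolume),
               sprintf("#temperature_K %.10g", exp@temperature),
               sprintf("#outer_fraction %.10g", exp@outerFraction),
               if (length(exp@provenance))
                 sprintf("#seed %s", exp@provenance$seed %||% "NA")),
             con)
  writeLines("injection_volume_ul,heat_uJ", con)
  writeLines(sprintf("%.10g,%.10g", exp@injectionVolumes, exp@heats), con)
  invisible(path)
}

#' Read and write titration traces
#'
#' Two-column CSV (\code{time_s,intensity}) with a comment header carrying
#' the baseline window, plus an events sidecar
#' (\code{time_s,label,dose_nmol}) at \code{<path>.events}.
#'
#' @param path file path of the trace.
#' @param trace A \linkS4class{TitrationTrace} (writer).
#' @return Reader: a \linkS4class{TitrationTrace}; writer: the path,
#'   invisibly.
#' @export
readTrace <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  baseline <- NULL
  for (h in hdr)
    if (startsWith(h, "#baseline"))
      baseline <- scan(text = sub("^#baseline ", "", h), quiet = TRUE)
  tab <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  evPath <- paste0(path, ".events")
  events <- if (file.exists(evPath)) {
    e <- utils::read.csv(evPath)
    data.frame(time = e$time_s, label = e$label, dose = e$dose_nmol)
  } else data.frame(time = numeric(), label = character(), dose = numeric())
  TitrationTrace(tab$time_s, tab$intensity, events = events,
                 baseline = baseline %||% range(tab$time_s))
}

#' @rdname readTrace
#' @export
writeTrace <- function(trace, path) {
  con <- file(path, "w")
  writeLines(sprintf("#baseline %.10g %.10g", trace@baseline[1],
                     trace@baseline[2]), con)
  if (length(trace@provenance))
    writeLines(sprintf("#seed %s", trace@provenance$seed %||% "NA"), con)
  writeLines("time_s,intensity", con)
  writeLines(sprintf("%.10g,%.10g", trace@time, trace@intensity), con)
  close(con)
  if (nrow(trace@events)) {
    e <- trace@events
    utils::write.csv(data.frame(time_s = e$time, label = e$label,
                                dose_nmol = e$dose),
                     paste0(path, ".events"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
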