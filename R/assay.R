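#' Drug inhibition rate from MTT optical densities
#'
#' `1 - (OD_compound - OD_blank) / (OD_DMSO - OD_blank)`: 0 means the
#' treated well matches the vehicle control (no inhibition), 1 means it
#' matches the blank (complete inhibition).  Negative values indicate
#' growth promotion.  Vectorized over its arguments.
#'
#' @param od_compound Optical density of the drug-treated well(s).
#' @param od_dmso Optical density of the DMSO vehicle control.
#' @param od_blank Optical density of the blank well.
#' @return Inhibition rate(s).
#' @export
inhibition_rate <- function(od_compound, od_dmso, od_blank) {
  if (any(od_dmso == od_blank))
    stop("od_dmso equals od_blank: inhibition rate undefined",
         call. = FALSE)
  1 - (od_compound - od_blank) / (od_dmso - od_blank)
}

#' Construct a dose-response record
#'
#' One drug on one cell line: replicate OD readings at each tested
#' concentration, plus vehicle-control and blank readings.
#'
#' @param drug_id,cell_line Identifiers.
#' @param concentrations Numeric vector of tested concentrations
#'   (mg/mL), one per row of `od_compound`.
#' @param od_compound Numeric matrix of treated-well ODs, one row per
#'   concentration, one column per replicate.
#' @param od_dmso Numeric vector of vehicle-control replicate ODs.
#' @param od_blank Blank OD (scalar).
#' @return Object of class `"dose_response"`.
#' @export
dose_response <- function(drug_id, cell_line, concentrations,
                          od_compound, od_dmso, od_blank) {
  od_compound <- as.matrix(od_compound)
  if (length(concentrations) != nrow(od_compound))
    stop("one row of od_compound per concentration required",
         call. = FALSE)
  if (ncol(od_compound) < 1L || length(od_dmso) < 1L)
    stop("at least one replicate required", call. = FALSE)
  .assert_scalar_number(od_blank, "od_blank")
  if (mean(od_dmso) == od_blank)
    stop("mean DMSO OD equals blank OD", call. = FALSE)
  structure(list(drug_id = drug_id, cell_line = cell_line,
                 concentrations = as.numeric(concentrations),
                 od_compound = od_compound, od_dmso = as.numeric(od_dmso),
                 od_blank = od_blank),
            class = "dose_response")
}

#' Summarize a dose-response record
#'
#' The inhibition rate is computed per replicate (against the mean
#' vehicle-control OD and the blank), then averaged per concentration;
#' the spread is the sample standard deviation over replicates.  Rows
#' are ordered by increasing concentration.
#'
#' @param dr A [dose_response()] object.
#' @return Data frame with columns `drug_id`, `cell_line`,
#'   `concentration`, `n_replicates`, `mean_inhibition`,
#'   `sd_inhibition`.
#' @export
summarize_dose_response <- function(dr) {
  stopifnot(inherits(dr, "dose_response"))
  rates <- inhibition_rate(dr$od_compound, mean(dr$od_dmso), dr$od_blank)
  n_rep <- ncol(dr$od_compound)
  if (n_rep == 1L) {
    warning("single replicate: sd reported as 0", call. = FALSE)
    sds <- rep(0, nrow(rates))
  } else {
    sds <- apply(rates, 1L, sd)
  }
  out <- data.frame(drug_id = dr$drug_id, cell_line = dr$cell_line,
                    concentration = dr$concentrations,
                    n_replicates = n_rep,
                    mean_inhibition = rowMeans(rates),
                    sd_inhibition = sds,
                    stringsAsFactors = FALSE)
  out[order(out$concentration), , drop = FALSE]
}

#' Read MTT assay readings from a TSV file
#'
#' Expected columns: `drug_id`, `cell_line`, `concentration`,
#' `replicate`, `od`.  Control rows use `drug_id` `"DMSO"` (vehicle,
#' per cell line) and `"BLANK"` (blank, `cell_line` ignored).  Returns
#' one [dose_response()] per drug/cell-line combination.
#'
#' @param path Readings TSV.
#' @return Named list of `dose_response` objects
#'   (`"<drug_id>|<cell_line>"`).
#' @export
read_mtt_readings <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  req <- c("drug_id", "cell_line", "concentration", "replicate", "od")
  if (!all(req %in% names(tab)))
    stop("readings file must contain columns ",
         paste(req, collapse = ", "), call. = FALSE)
  blank <- tab[tab$drug_id == "BLANK", , drop = FALSE]
  if (nrow(blank) == 0L) stop("no BLANK rows", call. = FALSE)
  od_blank <- mean(blank$od)
  dmso <- tab[tab$drug_id == "DMSO", , drop = FALSE]
  if (nrow(dmso) == 0L) stop("no DMSO rows", call. = FALSE)
  drug_rows <- tab[!tab$drug_id %in% c("DMSO", "BLANK"), , drop = FALSE]
  combos <- unique(drug_rows[, c("drug_id", "cell_line")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    d <- combos$drug_id[i]; cl <- combos$cell_line[i]
    sub <- drug_rows[drug_rows$drug_id == d & drug_rows$cell_line == cl, ]
    concs <- sort(unique(sub$concentration))
    reps <- sort(unique(sub$replicate))
    od <- matrix(NA_real_, length(concs), length(reps))
    od[cbind(match(sub$concentration, concs),
             match(sub$replicate, reps))] <- sub$od
    if (anyNA(od))
      stop("incomplete replicate grid for ", d, " on ", cl, call. = FALSE)
    ctrl <- dmso$od[dmso$cell_line == cl]
    if (length(ctrl) == 0L) ctrl <- dmso$od
    dose_response(d, cl, concs, od, ctrl, od_blank)
  })
  setNames(out, paste(combos$drug_id, combos$cell_line, sep = "|"))
}
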