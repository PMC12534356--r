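#' Water sample collections
#'
#' A `pem_samples` object holds an ordered collection of water samples:
#' per-site metadata (group label, optional downstream distance, pH) and a
#' long table of per-analyte measurements. A measurement is either an
#' observed concentration (µg/L) or left-censored, i.e. known only to lie
#' below a positive detection limit. All concentrations are µg/L throughout
#' the package; the health-risk module converts to mg/L at its boundary.
#'
#' @param sites data.frame with columns `site_id`, `group` (one of
#'   [pem_groups()]), `distance_km` (NA except for main-stem sites) and
#'   `pH`; an optional `site_name` column is kept if present.
#' @param conc long data.frame with columns `site_id`, `analyte`, `value`
#'   (numeric, NA when censored), `censored` (logical) and
#'   `detection_limit` (numeric, NA unless censored).
#' @param censor_policy policy descriptor; `"raw"` for freshly read data,
#'   otherwise the policy applied by [resolve_censored()].
#'
#' @return An object of class `pem_samples`.
#' @seealso [read_pem_samples()], [nyamwamba_waters()], [resolve_censored()]
#' @export
pem_samples <- function(sites, conc, censor_policy = "raw") {
  sites <- as.data.frame(sites)
  conc <- as.data.frame(conc)
  need_sites <- c("site_id", "group", "pH")
  if (!all(need_sites %in% names(sites))) {
    stop("`sites` must have columns: ", paste(need_sites, collapse = ", "))
  }
  if (!"distance_km" %in% names(sites)) sites$distance_km <- NA_real_
  if (!"site_name" %in% names(sites)) sites$site_name <- NA_character_
  need_conc <- c("site_id", "analyte", "value", "censored", "detection_limit")
  if (!all(need_conc %in% names(conc))) {
    stop("`conc` must have columns: ", paste(need_conc, collapse = ", "))
  }
  if (anyDuplicated(sites$site_id)) {
    stop("duplicate site_id: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "))
  }
  bad_group <- setdiff(unique(sites$group), pem_groups())
  if (length(bad_group)) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  }
  if (any(!is.na(sites$pH) & (sites$pH < 0 | sites$pH > 14))) {
    stop("pH out of [0, 14]")
  }
  bad_an <- setdiff(unique(conc$analyte), pem_analytes())
  if (length(bad_an)) {
    stop("unknown analyte(s): ", paste(bad_an, collapse = ", "))
  }
  if (any(!conc$site_id %in% sites$site_id)) {
    stop("concentration rows for unknown site_id")
  }
  validate_measurements(conc, raw = identical(censor_policy, "raw"))
  sites <- sites[, c("site_id", "site_name", "group", "distance_km", "pH")]
  structure(
    list(sites = sites, conc = conc, censor_policy = censor_policy),
    class = "pem_samples"
  )
}

# Raw measurements: exactly one of {value present, censored}. Resolved sets
# may carry censored = TRUE alongside a substituted value (policy record).
validate_measurements <- function(conc, raw = TRUE) {
  if (any(!is.na(conc$value) & conc$value < 0)) {
    stop("negative concentration value(s)")
  }
  if (any(conc$censored & (is.na(conc$detection_limit) | conc$detection_limit <= 0))) {
    stop("censored measurement without a positive detection_limit")
  }
  if (raw) {
    one_of <- xor(!is.na(conc$value), conc$censored)
    if (!all(one_of)) {
      stop("raw measurement must be exactly one of {observed value, censored}")
    }
  }
  invisible(conc)
}

#' @export
print.pem_samples <- function(x, ...) {
  tab <- table(factor(x$sites$group, levels = pem_groups()))
  cat(sprintf(
    "<pem_samples> %d sites (%s), %d analytes, censor policy: %s\n",
    nrow(x$sites),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    length(unique(x$conc$analyte)), x$censor_policy
  ))
  ncen <- sum(x$conc$censored)
  cat(sprintf("  %d of %d measurements censored (<DL)\n", ncen, nrow(x$conc)))
  invisible(x)
}

#' @export
length.pem_samples <- function(x) nrow(x$sites)

#' Read a delimited concentration table
#'
#' Reads a wide site-by-analyte table: one row per site, analyte columns in
#' µg/L, censored cells written as `"<x"` where `x` is the detection limit.
#' Expected columns: `site_id`, `group`, `pH`, any of [pem_analytes()];
#' optional `site_name` and `distance_km`. Any other column is rejected.
#'
#' @param path file path (or connection) of the comma/tab separated table.
#' @param sep field separator, `","` by default.
#' @return A raw [pem_samples] object (`censor_policy = "raw"`).
#' @export
read_pem_samples <- function(path, sep = ",") {
  wide <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character", na.strings = "NA")
  pem_samples_from_wide(wide)
}

pem_samples_from_wide <- function(wide) {
  meta_cols <- c("site_id", "site_name", "group", "distance_km", "pH")
  if (!all(c("site_id", "group", "pH") %in% names(wide))) {
    stop("table must have site_id, group and pH columns")
  }
  analyte_cols <- setdiff(names(wide), meta_cols)
  unknown <- setdiff(analyte_cols, pem_analytes())
  if (length(unknown)) {
    stop("unknown analyte column(s): ", paste(unknown, collapse = ", "))
  }
  n <- nrow(wide)
  sites <- data.frame(
    site_id = as.character(wide$site_id),
    site_name = if ("site_name" %in% names(wide)) as.character(wide$site_name)
                else rep(NA_character_, n),
    group = as.character(wide$group),
    distance_km = if ("distance_km" %in% names(wide)) as.numeric(wide$distance_km)
                  else rep(NA_real_, n),
    pH = as.numeric(wide$pH),
    stringsAsFactors = FALSE
  )
  conc_list <- lapply(analyte_cols, function(a) {
    cells <- trimws(as.character(wide[[a]]))
    m <- parse_measurements(cells, analyte = a, sites = sites$site_id)
    m$analyte <- a
    m
  })
  conc <- do.call(rbind, conc_list)
  if (is.null(conc)) {
    conc <- data.frame(site_id = character(), analyte = character(),
                       value = numeric(), censored = logical(),
                       detection_limit = numeric(), stringsAsFactors = FALSE)
  } else {
    conc <- conc[order(match(conc$site_id, sites$site_id),
                       match(conc$analyte, pem_analytes())), , drop = FALSE]
    rownames(conc) <- NULL
    conc <- conc[, c("site_id", "analyte", "value", "censored", "detection_limit")]
  }
  pem_samples(sites, conc, censor_policy = "raw")
}

# "<x" convention: a leading "<" marks a left-censored cell with detection
# limit x. Empty cells are dropped (analyte not measured at that site).
parse_measurements <- function(cells, analyte, sites) {
  keep <- !is.na(cells) & nzchar(cells)
  cells <- cells[keep]
  sites <- sites[keep]
  censored <- startsWith(cells, "<")
  value <- rep(NA_real_, length(cells))
  dl <- rep(NA_real_, length(cells))
  value[!censored] <- as.numeric(cells[!censored])
  dl[censored] <- as.numeric(sub("^<\\s*", "", cells[censored]))
  if (anyNA(value[!censored]) || anyNA(dl[censored])) {
    stop("unparseable ", analyte, " cell(s): ",
         paste(cells[(!censored & is.na(value)) | (censored & is.na(dl))],
               collapse = ", "))
  }
  if (any(value[!censored] < 0)) {
    stop("negative ", analyte, " concentration at site(s): ",
         paste(sites[!censored & value < 0], collapse = ", "))
  }
  data.frame(site_id = sites, value = value, censored = censored,
             detection_limit = dl, stringsAsFactors = FALSE)
}

#' Write a sample set to the delimited format
#'
#' Inverse of [read_pem_samples()]: censored measurements are written back
#' as `"<x"` strings, so a raw set round-trips exactly.
#'
#' @param x a [pem_samples] object.
#' @param path output file path.
#' @param sep field separator.
#' @return `x`, invisibly.
#' @export
write_pem_samples <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "pem_samples"))
  analytes <- intersect(pem_analytes(), unique(x$conc$analyte))
  wide <- x$sites
  for (a in analytes) {
    rows <- x$conc[x$conc$analyte == a, ]
    cell <- rep(NA_character_, nrow(wide))
    idx <- match(rows$site_id, wide$site_id)
    cell[idx] <- ifelse(rows$censored & is.na(rows$value),
                        paste0("<", format_num(rows$detection_limit)),
                        format_num(rows$value))
    wide[[a]] <- cell
  }
  utils::write.table(wide, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(x)
}

format_num <- function(v) {
  vapply(v, function(z) if (is.na(z)) NA_character_ else format(z, scientific = FALSE, trim = TRUE), "")
}

#' Resolve censored measurements
#'
#' Replaces every left-censored measurement according to a substitution
#' policy and records the policy on the returned set. The input set is
#' untouched, uncensored values are never altered, and applying the
#' operation again is a no-op.
#'
#' Policies: `"half_dl"` substitutes half the detection limit (the package
#' default everywhere, and the policy under which the fixture background
#' values reproduce); `"zero"` and `"dl"` substitute 0 and the detection
#' limit; `"drop"` removes censored measurements entirely, so any
#' downstream stage that needs the analyte at that site fails loudly.
#'
#' @param x a [pem_samples] object with `censor_policy = "raw"` (a set
#'   already resolved under the same policy passes through unchanged).
#' @param policy one of `"half_dl"`, `"zero"`, `"dl"`, `"drop"`.
#' @return A resolved [pem_samples] object.
#' @export
resolve_censored <- function(x, policy = c("half_dl", "zero", "dl", "drop")) {
  stopifnot(inherits(x, "pem_samples"))
  policy <- match.arg(policy)
  if (identical(x$censor_policy, policy)) return(x)
  if (!identical(x$censor_policy, "raw")) {
    stop("sample set already resolved under policy '", x$censor_policy, "'")
  }
  conc <- x$conc
  cen <- conc$censored
  if (policy == "drop") {
    conc <- conc[!cen, , drop = FALSE]
  } else {
    sub <- switch(policy,
      half_dl = conc$detection_limit[cen] / 2,
      zero = 0,
      dl = conc$detection_limit[cen]
    )
    conc$value[cen] <- sub
  }
  rownames(conc) <- NULL
  out <- x
  out$conc <- conc
  out$censor_policy <- policy
  out
}

#' Subset a sample collection by group
#'
#' Order-preserving filter of a sample set by its group labels.
#'
#' @param x a [pem_samples] object.
#' @param groups nonempty character vector of group labels
#'   (see [pem_groups()]); unknown labels are rejected.
#' @return A [pem_samples] object with only the matching sites.
#' @export
pem_subset <- function(x, groups) {
  stopifnot(inherits(x, "pem_samples"))
  if (!length(groups)) stop("`groups` must be nonempty")
  bad <- setdiff(groups, pem_groups())
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  keep <- x$sites$group %in% groups
  if (!any(keep)) {
    warning("no sites in group(s): ", paste(groups, collapse = ", "))
  }
  out <- x
  out$sites <- x$sites[keep, , drop = FALSE]
  out$conc <- x$conc[x$conc$site_id %in% out$sites$site_id, , drop = FALSE]
  rownames(out$sites) <- rownames(out$conc) <- NULL
  out
}

#' Resolved concentration matrix
#'
#' Sites-by-analytes numeric matrix of resolved concentrations (µg/L).
#' Errors if the set still contains unresolved censored measurements or if
#' a requested analyte is missing at some site (e.g. after policy
#' `"drop"`), so censoring is never silently ignored downstream.
#'
#' @param x a resolved [pem_samples] object.
#' @param analytes analytes to extract (default: those present).
#' @return Numeric matrix with site_id rownames and analyte colnames.
#' @export
conc_matrix <- function(x, analytes = NULL) {
  stopifnot(inherits(x, "pem_samples"))
  if (identical(x$censor_policy, "raw") && any(x$conc$censored)) {
    stop("sample set contains unresolved censored measurements; ",
         "call resolve_censored() first")
  }
  if (is.null(analytes)) {
    analytes <- intersect(pem_analytes(), unique(x$conc$analyte))
  }
  m <- matrix(NA_real_, nrow(x$sites), length(analytes),
              dimnames = list(x$sites$site_id, analytes))
  rows <- x$conc[x$conc$analyte %in% analytes, ]
  m[cbind(match(rows$site_id, x$sites$site_id),
          match(rows$analyte, analytes))] <- rows$value
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing resolved concentration for ",
         paste(unique(colnames(m)[bad[, 2]]), collapse = ", "),
         " (was the analyte dropped under censoring policy '",
         x$censor_policy, "'?)")
  }
  m
}

#' River Nyamwamba survey fixture
#'
#' The packaged 19-sample dry-season survey of the Nyamwamba catchment:
#' nine main-stem sites (NY-01 upstream of the mining area to NY-15
#' downstream), five tributaries, the underground mine drainage channel
#' (NY-06) and four Lake George sites, with pH and dissolved (< 0.45 µm)
#' concentrations of twelve PEMs. Cd and Cr were below their detection
#' limits (0.29 and 0.05 µg/L) in every sample and are carried as fully
#' censored columns. Censoring is preserved (`censor_policy = "raw"`).
#'
#' Two typographic ambiguities in the source table are resolved in the
#' shipped values and noted here: NY-01 Cu = 1.91 and Fe = 130 µg/L (forced
#' by the published background and mean rows), and the Kyanzusu tributary
#' Fe is stored as 415 µg/L (the table value; the narrative text says 416).
#'
#' @return A raw [pem_samples] object with 19 sites.
#' @export
nyamwamba_waters <- function() {
  path <- system.file("extdata", "nyamwamba_waters.csv", package = "pemriver",
                      mustWork = TRUE)
  read_pem_samples(path)
}
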