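#' Read a parasite-host-area association table
#'
#' Reads a UTF-8 tab-separated table with one host per row and the columns
#' `parasite_lineage`, `parasite_rank`, `host_code`, `host_species`,
#' `host_tribe`, `area_code`, `area_name`, `hydrological_system`.
#' Printed tables often list several hosts in one cell; the on-disk format
#' is the normalised long form, one record per (lineage, host, area).
#'
#' Validation enforces: no empty fields; `parasite_rank` in
#' `{species, lineage}`; host codes are single lowercase letters and area
#' codes single uppercase letters; codes are consistent (one species per
#' code and vice versa); tribes are known goodeine tribes or
#' `non-goodeid:<family>`; no duplicated (lineage, host, area) triple.
#'
#' @param path Path to the TSV file.  Lines starting with `#` are ignored.
#' @param registry Optional list with elements `hosts` and `areas` (as
#'   returned by [margotrema_host_registry()] and
#'   [margotrema_area_registry()]); when supplied, every code/name pair in
#'   the table must appear in the registry.
#' @return A data frame of class `association_table` with the columns
#'   above and attributes `n_areas`, `n_hosts`, `n_lineages`.
#' @examples
#' tab <- margotrema_associations()
#' attr(tab, "n_areas")   # 12
#' attr(tab, "n_hosts")   # 15
#' @export
read_association_table <- function(path, registry = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", fileEncoding = "UTF-8")
  required <- c("parasite_lineage", "parasite_rank", "host_code",
                "host_species", "host_tribe", "area_code", "area_name",
                "hydrological_system")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("association table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, required]
  validate_association_table(tab, registry = registry)
}

#' @rdname read_association_table
#' @param table A data frame with the association-table columns.
#' @export
validate_association_table <- function(table, registry = NULL) {
  if (nrow(table) == 0) {
    stop("association table is empty", call. = FALSE)
  }
  for (col in names(table)) {
    bad <- is.na(table[[col]]) | !nzchar(trimws(table[[col]]))
    if (any(bad)) {
      stop(sprintf("association table has empty '%s' in row(s) %s",
                   col, paste(which(bad), collapse = ", ")), call. = FALSE)
    }
  }
  if (!all(table$parasite_rank %in% c("species", "lineage"))) {
    stop("parasite_rank must be 'species' or 'lineage'", call. = FALSE)
  }
  if (!all(grepl("^[a-z]$", table$host_code))) {
    stop("host codes must be single lowercase letters", call. = FALSE)
  }
  if (!all(grepl("^[A-Z]$", table$area_code))) {
    stop("area codes must be single uppercase letters", call. = FALSE)
  }
  bad_tribe <- !is_valid_tribe(table$host_tribe)
  if (any(bad_tribe)) {
    stop("unknown tribe label(s): ",
         paste(unique(table$host_tribe[bad_tribe]), collapse = ", "),
         call. = FALSE)
  }
  # a code must always denote the same species/area and conversely
  check_bijection <- function(code, name, what) {
    per_code <- tapply(name, code, function(x) length(unique(x)))
    per_name <- tapply(code, name, function(x) length(unique(x)))
    if (any(per_code > 1) || any(per_name > 1)) {
      stop(sprintf("%s codes are not one-to-one with %s names", what, what),
           call. = FALSE)
    }
  }
  check_bijection(table$host_code, table$host_species, "host")
  check_bijection(table$area_code, table$area_name, "area")
  key <- paste(table$parasite_lineage, table$host_code, table$area_code)
  if (anyDuplicated(key)) {
    stop("duplicated (lineage, host, area) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  if (!is.null(registry)) {
    hk <- paste(table$host_code, table$host_species)
    hr <- paste(registry$hosts$host_code, registry$hosts$host_species)
    ak <- paste(table$area_code, table$area_name)
    ar <- paste(registry$areas$area_code, registry$areas$area_name)
    if (!all(hk %in% hr)) {
      stop("host record(s) not in registry: ",
           paste(unique(hk[!hk %in% hr]), collapse = "; "), call. = FALSE)
    }
    if (!all(ak %in% ar)) {
      stop("area record(s) not in registry: ",
           paste(unique(ak[!ak %in% ar]), collapse = "; "), call. = FALSE)
    }
  }
  attr(table, "n_areas") <- length(unique(table$area_code))
  attr(table, "n_hosts") <- length(unique(table$host_code))
  attr(table, "n_lineages") <- length(unique(table$parasite_lineage))
  class(table) <- c("association_table", "data.frame")
  table
}

#' The packaged Margotrema-Goodeinae association table
#'
#' Loads the parasite-host-area associations of the four *Margotrema*
#' species/lineages across 15 goodeine (plus one cyprinid) host species
#' and 12 hydrological sub-basins of central Mexico, in normalised long
#' form (printed cells listing two hosts are expanded to one record each).
#'
#' @return A validated `association_table` (see
#'   [read_association_table()]); 17 records, 12 areas, 15 hosts, 4
#'   parasite lineages.
#' @export
margotrema_associations <- function() {
  path <- system.file("extdata", "margotrema_associations.tsv",
                      package = "decophy", mustWork = TRUE)
  read_association_table(
    path,
    registry = list(hosts = margotrema_host_registry(),
                    areas = margotrema_area_registry())
  )
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf(
    "Parasite-host-area association table: %d records, %d areas, %d hosts, %d parasite lineages\n",
    nrow(x), attr(x, "n_areas"), attr(x, "n_hosts"), attr(x, "n_lineages")))
  print.data.frame(x, ...)
  invisible(x)
}
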