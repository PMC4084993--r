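#' Code registries for the Margotrema--Goodeinae system
#'
#' The biogeographic and cophylogenetic analyses code the 12 hydrological
#' sub-basins of central Mexico as uppercase letters A--L and the 15 host
#' fish species as lowercase letters a--o.  These registries are the
#' authoritative mapping used to validate association tables.
#'
#' @return `margotrema_area_registry()` returns a data frame with columns
#'   `area_code`, `area_name`, `hydrological_system`;
#'   `margotrema_host_registry()` returns a data frame with columns
#'   `host_code`, `host_species`, `host_tribe`.
#' @examples
#' margotrema_area_registry()
#' @export
margotrema_area_registry <- function() {
  data.frame(
    area_code = LETTERS[1:12],
    area_name = c(
      "Lower Conchos River",
      "Upper and Middle Mezquital River",
      "Lower Lerma River",
      "Zacapu Lake",
      "Cuitzeo Lake",
      "Pátzcuaro Lake",
      "Zirahuén Lake",
      "Armería-Ayuquila River",
      "Cuzalapa River",
      "Cotija",
      "Lower Balsas River",
      "Upper Balsas River"
    ),
    hydrological_system = c(
      "Conchos River Basin",
      "Mezquital River Basin",
      "Lerma River Basin",
      "Lerma River Basin",
      "Lerma River Basin",
      "Lerma River Basin",
      "Lerma River Basin",
      "Ayuquila River",
      "Cuzalapa River",
      "Lerma River Basin",
      "Balsas River Basin",
      "Balsas River Basin"
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname margotrema_area_registry
#' @export
margotrema_host_registry <- function() {
  data.frame(
    host_code = letters[1:15],
    host_species = c(
      "Allotoca diazi",
      "Allotoca duguesi",
      "Allotoca meeki",
      "Neoophorus regalis",
      "Alloophorus robustus",
      "Allotoca zacapuensis",
      "Allodontichthys zonistius",
      "Codoma ornata",
      "Characodon audax",
      "Chapalichthys pardalis",
      "Ilyodon furcidens",
      "Ilyodon whitei",
      "Xenotaenia resolanae",
      "Zoogoneticus quitzeoensis",
      "Zoogoneticus purhepechus"
    ),
    host_tribe = c(
      "Girardinichthyini",
      "Girardinichthyini",
      "Girardinichthyini",
      "Girardinichthyini",
      "Chapalichthyini",
      "Girardinichthyini",
      "Ilyodontini",
      "non-goodeid:Cyprinidae",
      "Characodontini",
      "Chapalichthyini",
      "Ilyodontini",
      "Ilyodontini",
      "Ilyodontini",
      "Chapalichthyini",
      "Chapalichthyini"
    ),
    stringsAsFactors = FALSE
  )
}

# Goodeine tribes recognised for level classification; anything matching
# "non-goodeid:<family>" is an explicit out-group flag.
goodeine_tribes <- c(
  "Ilyodontini", "Characodontini", "Chapalichthyini", "Girardinichthyini"
)

is_valid_tribe <- function(x) {
  x %in% goodeine_tribes | grepl("^non-goodeid:.+$", x)
}
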