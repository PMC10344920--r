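#' Tracked nutrients and sector vocabularies
#'
#' The pipeline tracks seven nutrients measured per 100 g of edible raw muscle
#' tissue: iron (mg), zinc (mg), calcium (mg), vitamin A (ug RAE),
#' vitamin B12 (ug), DHA+EPA (g) and protein (g). Six of them — everything but
#' protein — form the "assessed" set used for country means and
#' classification. Catch sectors follow the reconstructed-catch convention:
#' artisanal (small-scale commercial), subsistence (small-scale
#' non-commercial), industrial (large-scale commercial), recreational, and
#' mariculture (marine aquaculture); small-scale fisheries (SSF) are artisanal
#' plus subsistence. Apparent-consumption tables add a sixth source-sector,
#' `imports`, resolved only to commodity category.
#'
#' @name vocabularies
#' @keywords internal
NULL

NUTRIENTS <- c("iron", "zinc", "calcium", "vitamin_a", "vitamin_b12",
               "dha_epa", "protein")

ASSESSED_NUTRIENTS <- setdiff(NUTRIENTS, "protein")

TAXON_RANKS <- c("scientific_name", "genus", "family", "order", "class")

MATCH_LEVELS <- c("species", "genus", "family", "order", "class", "commodity")

# rank column consulted at each fallback level
LEVEL_COLUMNS <- c(species = "scientific_name", genus = "genus",
                   family = "family", order = "order", class = "class",
                   commodity = "commodity")

CATCH_SECTORS <- c("artisanal", "subsistence", "industrial", "recreational",
                   "mariculture")
COMMERCIAL_SECTORS <- c("artisanal", "industrial")
NONCOMMERCIAL_SECTORS <- c("subsistence", "recreational")
SSF_SECTORS <- c("artisanal", "subsistence")
SOURCE_SECTORS <- c(CATCH_SECTORS, "imports")

END_USES <- c("direct_human_consumption", "fishmeal_fish_oil", "discard")

# non-seafood animal-sourced food groups as reported in global nutrient
# supply accounts (fish itself enters through the seafood sectors)
ANIMAL_GROUPS <- c("beef", "veal", "pork", "dairy", "poultry", "sheep")

OTHER_FOOD_GROUPS <- c("grains", "vegetables", "fruits", "pulses", "oils")

CONTRIBUTION_SCOPES <- c("seafood", "animal_sourced", "all_foods")

COMMODITIES <- c("pelagic_fish", "demersal_fish", "other_marine_fish",
                 "crustaceans", "molluscs", "cephalopods")

CRUSTACEAN_COMMODITY <- "crustaceans"

BUFFER_DISTANCES_KM <- c(5, 10, 20, 30, 40, 50)
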