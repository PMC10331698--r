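#' Endpoint vocabulary
#'
#' An endpoint vocabulary describes every biomarker endpoint of a screening
#' panel: one row per endpoint with its cell system, biomarker label, readout
#' direction and functional roles. Endpoint identifiers use the canonical
#' `"SYSTEM:Biomarker"` key (e.g. `"3C:SRB"`, `"BT:sIgG"`).
#'
#' @details
#' The twelve recognized co-culture systems are `3C`, `4H`, `LPS`, `SAg`,
#' `BT`, `BE3C`, `BF4T`, `HDF3CGF`, `KF3CT`, `CASM3C`, `MyoF` and `Mphg`.
#' Systems `3C`, `4H`, `LPS` and `Mphg` contain endothelial cells, which
#' matters for the acute-toxicity signature. Roles are drawn from
#' `srb_total_protein` (SRB total-protein viability stains),
#' `pbmc_cytotoxicity` (suspension-cell viability), `proliferation`,
#' `igg_secretion` and the catch-all `biomarker`. Loss-of-signal endpoints
#' carry `is_down = TRUE` and have their sign inverted before hit calling so
#' that all detectable responses point in the positive direction.
#'
#' @param system character vector of system codes.
#' @param biomarker character vector of biomarker labels, same length.
#' @param is_down logical; `TRUE` for loss-of-signal readouts.
#' @param roles character; one role per endpoint (multiple roles may be
#'   joined with `";"`).
#' @return A `data.frame` of class `endpoint_vocabulary` with columns
#'   `endpoint_id`, `system`, `biomarker`, `is_down`, `roles`,
#'   `is_endothelial_system`.
#' @seealso [default_endpoints()] for the stock 148-endpoint panel.
#' @export
endpoint_vocabulary <- function(system, biomarker, is_down, roles) {
  stopifnot(length(system) == length(biomarker),
            length(system) == length(is_down),
            length(system) == length(roles))
  bad <- setdiff(unique(system), PANEL_SYSTEMS)
  if (length(bad) > 0L) {
    stop("unknown system code(s): ", paste(bad, collapse = ", "))
  }
  vocab <- data.frame(
    endpoint_id = paste0(system, ":", biomarker),
    system = system,
    biomarker = biomarker,
    is_down = as.logical(is_down),
    roles = roles,
    is_endothelial_system = system %in% ENDOTHELIAL_SYSTEMS,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(vocab$endpoint_id)) {
    stop("duplicate endpoint_id in vocabulary: ",
         paste(vocab$endpoint_id[duplicated(vocab$endpoint_id)], collapse = ", "))
  }
  class(vocab) <- c("endpoint_vocabulary", "data.frame")
  vocab
}

#' The twelve panel systems and the endothelial subset
#' @rdname endpoint_vocabulary
#' @export
PANEL_SYSTEMS <- c("3C", "4H", "LPS", "SAg", "BT", "BE3C", "BF4T",
                   "HDF3CGF", "KF3CT", "CASM3C", "MyoF", "Mphg")

#' @rdname endpoint_vocabulary
#' @export
ENDOTHELIAL_SYSTEMS <- c("3C", "4H", "LPS", "Mphg")

ENDPOINT_ROLES <- c("srb_total_protein", "pbmc_cytotoxicity", "proliferation",
                    "igg_secretion", "biomarker")

role_for_biomarker <- function(biomarker) {
  ifelse(biomarker == "SRB", "srb_total_protein",
  ifelse(biomarker == "PBMC Cytotoxicity", "pbmc_cytotoxicity",
  ifelse(biomarker == "Proliferation", "proliferation",
  ifelse(biomarker == "sIgG", "igg_secretion", "biomarker"))))
}

#' Default 148-endpoint screening panel
#'
#' Builds the stock vocabulary used by the synthetic-screen generator and the
#' worked examples: 148 endpoints over the 12 co-culture systems, including
#' every endpoint the toxicity-signature rules consult (`3C:SRB`,
#' `3C:Proliferation`, `3C:TF`, `SAg:Proliferation`,
#' `SAg:PBMC Cytotoxicity`, `BT:sIgG`, `BT:Proliferation`,
#' `BT:PBMC Cytotoxicity`, `LPS:PGE2`, `LPS:sTNFa`,
#' `HDF3CGF:Collagen III`, `HDF3CGF:VCAM-1`, `CASM3C:SAA`) and an SRB
#' total-protein endpoint in every adherent system. The biomarker layout is a
#' synthetic stand-in for a commercial panel whose full endpoint list is not
#' redistributable; system codes, signature endpoints and role structure are
#' faithful. Greek letters in biomarker names are transliterated to ASCII
#' (`sTNFa`, `IL-1a`).
#'
#' @return An [endpoint_vocabulary()] with 148 rows.
#' @export
default_endpoints <- function() {
  panel <- list(
    `3C` = c("SRB", "Proliferation", "TF", "TM", "VCAM-1", "ICAM-1",
             "E-selectin", "MCP-1", "MIG", "IL-8", "HLA-DR", "uPAR"),
    `4H` = c("SRB", "MCP-1", "Eotaxin-3", "VCAM-1", "P-selectin", "uPAR",
             "VEGFR2", "IL-8"),
    LPS = c("SRB", "VCAM-1", "TM", "TF", "CD40", "E-selectin", "CD69",
            "IL-8", "IL-1a", "M-CSF", "PGE2", "sTNFa"),
    SAg = c("SRB", "PBMC Cytotoxicity", "Proliferation", "MCP-1", "MIG",
            "VCAM-1", "CD38", "CD40", "CD69", "E-selectin", "IL-8"),
    BT = c("sIgG", "Proliferation", "PBMC Cytotoxicity", "sIL-17A",
           "sIL-17F", "sIL-2", "sIL-6", "sTNFa"),
    BE3C = c("SRB", "HLA-DR", "IL-1a", "IP-10", "I-TAC", "IL-8", "MIG",
             "MMP-1", "MMP-9", "PAI-1", "tPA", "uPA", "Eotaxin-3"),
    BF4T = c("SRB", "MCP-1", "Eotaxin-3", "VCAM-1", "ICAM-1", "CD90",
             "IL-8", "IL-1a", "Keratin 8/18", "MMP-1", "MMP-3", "MMP-9",
             "PAI-1", "tPA", "uPA"),
    HDF3CGF = c("SRB", "Proliferation", "MCP-1", "VCAM-1", "ICAM-1",
                "Collagen I", "Collagen III", "IP-10", "I-TAC", "IL-8",
                "MIG", "MMP-1", "PAI-1", "TIMP-1", "TIMP-2", "EGFR"),
    KF3CT = c("SRB", "MCP-1", "ICAM-1", "IP-10", "IL-1a", "MMP-9",
              "PAI-1", "TIMP-2", "uPA", "TGFb1", "MMP-1", "Keratin 8/18"),
    CASM3C = c("SRB", "Proliferation", "SAA", "MCP-1", "VCAM-1", "TM",
               "TF", "uPAR", "IL-6", "IL-8", "MIG", "HLA-DR", "LDLR",
               "M-CSF", "PAI-1"),
    MyoF = c("SRB", "aSMA", "bFGF", "VCAM-1", "Collagen I", "Collagen III",
             "Collagen IV", "IL-8", "Decorin", "MMP-1", "PAI-1", "TIMP-1",
             "Fibronectin", "tPA"),
    Mphg = c("SRB", "MCP-1", "MIP-1a", "VCAM-1", "CD40", "CD69",
             "E-selectin", "IL-8", "IL-1a", "M-CSF", "sIL-10", "sTNFa")
  )
  system <- rep(names(panel), lengths(panel))
  biomarker <- unlist(panel, use.names = FALSE)
  roles <- role_for_biomarker(biomarker)
  # suppression-read endpoints: viability/proliferation/IgG stains plus the
  # immune-suppression cytokine readouts and fibroblast matrix outputs
  down_extra <- paste0(system, ":", biomarker) %in% c(
    "BT:sIL-17A", "BT:sIL-17F", "BT:sIL-2", "BT:sIL-6", "BT:sTNFa",
    "Mphg:sIL-10",
    "HDF3CGF:Collagen I", "HDF3CGF:Collagen III",
    "MyoF:Collagen I", "MyoF:Collagen III", "MyoF:Collagen IV"
  )
  is_down <- roles != "biomarker" | down_extra
  endpoint_vocabulary(system, biomarker, is_down, roles)
}

#' Endpoints carrying a given role
#'
#' @param vocabulary an [endpoint_vocabulary()].
#' @param role one or more role names; endpoints matching any are returned.
#' @return Character vector of endpoint ids.
#' @export
endpoints_with_role <- function(vocabulary, role) {
  hits <- vapply(strsplit(vocabulary$roles, ";", fixed = TRUE),
                 function(r) any(r %in% role), logical(1))
  vocabulary$endpoint_id[hits]
}

#' Cytotoxicity-role endpoints (SRB total protein and PBMC viability)
#' @rdname endpoints_with_role
#' @export
cytotox_endpoints <- function(vocabulary) {
  endpoints_with_role(vocabulary, c("srb_total_protein", "pbmc_cytotoxicity"))
}

srb_endpoints <- function(vocabulary) {
  endpoints_with_role(vocabulary, "srb_total_protein")
}
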