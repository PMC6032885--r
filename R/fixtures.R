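# Fixture encodings of the published Vps9-family survey: a reference
# eukaryote species tree and the per-taxon subfamily classification
# (paralogue counts) assembled from the survey's reported results. Counts
# encode facts stated in the survey text; rows for taxa whose counts are
# only shown graphically are conservative and editable by the user.

.FIXTURE_TAXA <- data.frame(
  taxon_id = c("Homo_sapiens", "Gallus_gallus", "Drosophila_melanogaster",
               "Monosiga_brevicollis", "Capsaspora_owczarzaki",
               "Saccharomyces_cerevisiae", "Mortierella_verticillata",
               "Fonticula_alba", "Thecamonas_trahens",
               "Dictyostelium_discoideum", "Acanthamoeba_castellanii",
               "Trichosphaerium_sp", "Mayorella_sp", "Sexangularia_sp",
               "Trypanosoma_brucei", "Bodo_saltans", "Naegleria_gruberi",
               "Giardia_intestinalis", "Arabidopsis_thaliana",
               "Cyanidioschyzon_merolae", "Galdieria_sulphuraria",
               "Guillardia_theta", "Ectocarpus_siliculosus",
               "Aureococcus_anophagefferens", "Plasmodium_falciparum",
               "Emiliania_huxleyi"),
  supergroup = c(rep("Holozoa", 5), rep("Fungi", 3), "Apusozoa",
                 rep("Amoebozoa", 5), rep("Excavata", 4),
                 rep("Archaeplastida", 3), "Cryptophyta",
                 rep("Stramenopila", 2), "Alveolata", "Haptophyta"),
  transcriptome = c(rep(FALSE, 11), TRUE, TRUE, TRUE, rep(FALSE, 12)),
  stringsAsFactors = FALSE)

.FIXTURE_NEWICK <- paste0(
  "(((((((Homo_sapiens:0.1,Gallus_gallus:0.1):0.05,",
  "Drosophila_melanogaster:0.15):0.1,(Monosiga_brevicollis:0.2,",
  "Capsaspora_owczarzaki:0.15):0.05):0.1,((Saccharomyces_cerevisiae:0.25,",
  "Mortierella_verticillata:0.2):0.05,Fonticula_alba:0.2):0.1):0.05,",
  "(Thecamonas_trahens:0.25,Apusomonas_proboscidea:0.25):0.1):0.05,",
  "((Dictyostelium_discoideum:0.25,Acanthamoeba_castellanii:0.25):0.05,",
  "((Trichosphaerium_sp:0.2,Sexangularia_sp:0.2):0.05,",
  "Mayorella_sp:0.25):0.05):0.1):0.1,(((Trypanosoma_brucei:0.2,",
  "Bodo_saltans:0.15):0.1,(Naegleria_gruberi:0.25,",
  "Giardia_intestinalis:0.35):0.05):0.1,(((Arabidopsis_thaliana:0.25,",
  "(Cyanidioschyzon_merolae:0.3,Galdieria_sulphuraria:0.3):0.1):0.05,",
  "Guillardia_theta:0.3):0.05,(((Ectocarpus_siliculosus:0.2,",
  "Aureococcus_anophagefferens:0.2):0.1,Plasmodium_falciparum:0.3):0.05,",
  "Emiliania_huxleyi:0.25):0.05):0.1):0.05);")

#' Reference eukaryote species tree fixture
#'
#' A hard-coded rooted tree spanning the seven coloured clade groups of the
#' published survey (Holozoa, Fungi, Apusozoa, Amoebozoa, Excavata,
#' Archaeplastida+Cryptophyta, SAR+Haptophyta), each with at least two
#' representative taxa, labelled with supergroups and eukaryote domains.
#' The root separates Amorphea from Excavata+Diaphoretickes; branch lengths
#' are schematic. Deterministic.
#'
#' @return A [species_tree()].
#' @export
fixture_eukaryote_tree <- function() {
  tr <- ape::read.tree(text = .FIXTURE_NEWICK)
  taxa <- rbind(.FIXTURE_TAXA,
                data.frame(taxon_id = "Apusomonas_proboscidea",
                           supergroup = "Apusozoa", transcriptome = FALSE,
                           stringsAsFactors = FALSE))
  species_tree(tr, taxa)
}

#' Character grouping for the Vps9 subfamily matrix
#'
#' Maps root (LECA-level) characters to matrix columns. The
#' Rabex5+GAPVD1 megaclade is one root character spanning its two resolved
#' subfamilies and the megaclade-fallback column. `vps9dcp = "united"`
#' encodes the alternative reading in which Vps9DCP and Alsin form a single
#' unresolved root clade.
#'
#' @param vps9dcp `"split"` (default: Vps9DCP1 and Alsin are separate root
#'   characters) or `"united"`.
#' @return Named list of column groups for [presence_matrix()].
#' @export
vps9_character_groups <- function(vps9dcp = c("split", "united")) {
  vps9dcp <- match.arg(vps9dcp)
  g <- list("Rabex5+GAPVD1" = c("Rabex5", "GAPVD1", "Rabex5+GAPVD1"),
            "Varp" = "Varp", "RIN" = "RIN")
  if (vps9dcp == "split") {
    g$Alsin <- "Alsin"
    g$Vps9DCP1 <- "Vps9DCP1"
  } else {
    g[["Alsin+Vps9DCP1"]] <- c("Alsin", "Vps9DCP1")
  }
  g
}

#' Reported per-taxon Vps9 subfamily classification fixture
#'
#' Hard-coded paralogue counts per taxon and subfamily as reported by the
#' survey: resolved Rabex5 and GAPVD1 orthologues, megaclade-fallback
#' Rabex5+GAPVD1 sequences, Varp, Alsin, Vps9DCP1, RIN, and sequences left
#' unclassified. Includes the three Vps9-free genome taxa (Giardia
#' intestinalis and the reduced red algae Cyanidioschyzon merolae and
#' Galdieria sulphuraria). Amoebozoan transcriptome taxa carry `NA` where
#' no sequence was found, since absence cannot be asserted from a
#' transcriptome.
#'
#' @inheritParams vps9_character_groups
#' @return A [presence_matrix()] with `character_groups` set by
#'   [vps9_character_groups()] (the `unclassified` column belongs to no
#'   root character).
#' @export
fixture_presence_matrix <- function(vps9dcp = c("split", "united")) {
  cols <- c("Rabex5", "GAPVD1", "Rabex5+GAPVD1", "Varp", "Alsin",
            "Vps9DCP1", "RIN", "unclassified")
  m <- rbind(
    Homo_sapiens                = c(1, 1, 0, 1, 2, 1, 3, 0),
    Gallus_gallus               = c(1, 1, 0, 1, 1, 1, 3, 0),
    Drosophila_melanogaster     = c(1, 1, 0, 1, 1, 1, 1, 0),
    Monosiga_brevicollis        = c(1, 1, 0, 1, 1, 1, 1, 0),
    Capsaspora_owczarzaki       = c(1, 1, 0, 1, 1, 0, 1, 0),
    Saccharomyces_cerevisiae    = c(1, 0, 0, 1, 0, 0, 0, 0),
    Mortierella_verticillata    = c(1, 0, 0, 0, 0, 0, 0, 0),
    Fonticula_alba              = c(1, 1, 0, 1, 0, 0, 0, 0),
    Thecamonas_trahens          = c(0, 0, 0, 1, 0, 0, 0, 0),
    Dictyostelium_discoideum    = c(2, 1, 0, 1, 0, 1, 0, 1),
    Acanthamoeba_castellanii    = c(0, 0, 1, 1, 0, 0, 0, 0),
    Trichosphaerium_sp          = c(NA, 1, NA, NA, 1, NA, NA, NA),
    Mayorella_sp                = c(NA, NA, NA, NA, 1, NA, NA, NA),
    Sexangularia_sp             = c(NA, 1, 1, NA, 1, NA, NA, NA),
    Trypanosoma_brucei          = c(0, 0, 1, 0, 1, 0, 0, 0),
    Bodo_saltans                = c(0, 0, 0, 0, 1, 0, 0, 0),
    Naegleria_gruberi           = c(0, 1, 0, 0, 0, 0, 0, 2),
    Giardia_intestinalis        = c(0, 0, 0, 0, 0, 0, 0, 0),
    Arabidopsis_thaliana        = c(0, 0, 1, 1, 0, 0, 0, 0),
    Cyanidioschyzon_merolae     = c(0, 0, 0, 0, 0, 0, 0, 0),
    Galdieria_sulphuraria       = c(0, 0, 0, 0, 0, 0, 0, 0),
    Guillardia_theta            = c(0, 0, 1, 0, 0, 0, 0, 0),
    Ectocarpus_siliculosus      = c(0, 0, 1, 1, 0, 1, 0, 1),
    Aureococcus_anophagefferens = c(0, 0, 1, 0, 0, 1, 0, 0),
    Plasmodium_falciparum       = c(0, 0, 1, 0, 0, 0, 0, 0),
    Emiliania_huxleyi           = c(0, 0, 1, 1, 0, 1, 0, 0))
  colnames(m) <- cols
  presence_matrix(m, .FIXTURE_TAXA,
                  character_groups = vps9_character_groups(vps9dcp))
}

#' Convergent ANK+Vps9 architecture characters fixture
#'
#' Occurrences of the combined ankyrin-repeat-plus-Vps9 domain architecture
#' split into one character per phylogenetically distinct subfamily
#' context, as reported: opisthokont Varp orthologues; the Dictyostelium
#' discoideum ankyrin-ankyrin-Vps9 sequence excluded from the Varp clade;
#' and the stramenopile (Ectocarpus siliculosus, Aureococcus
#' anophagefferens) sequences grouping in the Rabex5+GAPVD1 clade.
#'
#' @return A [presence_matrix()] over the fixture taxa with one column per
#'   architecture-context character.
#' @export
fixture_architecture_characters <- function() {
  taxa <- .FIXTURE_TAXA
  n <- nrow(taxa)
  m <- matrix(0L, nrow = n, ncol = 3,
              dimnames = list(taxa$taxon_id,
                              c("ANK+Vps9|Varp|Opisthokonta",
                                "ANK+Vps9|lineage|Dictyostelium",
                                "ANK+Vps9|Rabex5+GAPVD1|Stramenopila")))
  m[c("Homo_sapiens", "Gallus_gallus", "Drosophila_melanogaster",
      "Monosiga_brevicollis", "Capsaspora_owczarzaki", "Fonticula_alba"),
    "ANK+Vps9|Varp|Opisthokonta"] <- 1L
  m["Dictyostelium_discoideum", "ANK+Vps9|lineage|Dictyostelium"] <- 1L
  m[c("Ectocarpus_siliculosus", "Aureococcus_anophagefferens"),
    "ANK+Vps9|Rabex5+GAPVD1|Stramenopila"] <- 1L
  m[taxa$transcriptome, ] <- NA_integer_
  presence_matrix(m, taxa)
}

#' Count taxa with complete data and no classified family member
#'
#' Genome (non-transcriptome) taxa whose classified-character counts are
#' all zero; transcriptome taxa are never counted since their absences are
#' unknown. The `unclassified` column, when present, must also be zero
#' (such taxa lack the family entirely).
#'
#' @param pm a [presence_matrix()].
#' @return Integer count.
#' @export
count_family_free_taxa <- function(pm) {
  genome <- !pm$taxa$transcriptome
  empty <- rowSums(pm$counts >= 1, na.rm = TRUE) == 0
  sum(genome & empty[match(pm$taxa$taxon_id, rownames(pm$counts))])
}
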