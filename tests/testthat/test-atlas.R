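# Pathway config loading and subject-table I/O.

test_that("the shipped default config defines the seven pathway networks", {
  paths <- defaultPathways()
  expect_length(paths, 7L)
  expect_setequal(names(paths),
                  c("striatocortical", "mesolimbic", "ch1_3", "ch4_medial",
                    "ch4_lateral_perisylvian", "ch4_lateral_capsular",
                    "ch5_6"))
  # anchor regions from the pathway descriptions
  expect_true(all(c("dorsal_caudate_L", "dorsal_putamen_R",
                    "somatosensory_L") %in%
                    roiNames(paths$striatocortical)))
  expect_true(all(c("amygdala_L", "parahippocampal_R") %in%
                    roiNames(paths$mesolimbic)))
  expect_true(all(c("hippocampus_L", "hypothalamus_R") %in%
                    roiNames(paths$ch1_3)))
  expect_true(all(c("thalamus_L", "pons", "midbrain", "medulla") %in%
                    roiNames(paths$ch5_6)))
  # the amygdala is shared between mesolimbic and Ch4 lateral capsular
  expect_true("amygdala_L" %in% roiNames(paths$ch4_lateral_capsular))
})

test_that("the default ROI universe is stable across releases", {
  union_rois <- sort(unique(unlist(lapply(defaultPathways(), roiNames))))
  expect_length(union_rois, 69L)
  golden <- sort(c(
    sprintf("%s_%s", rep(c(
      "dorsal_caudate", "dorsal_putamen", "premotor_frontal", "motor_cortex",
      "dorsolateral_prefrontal", "somatosensory",
      "ventral_striatum", "ventral_frontal", "medial_frontal",
      "anterior_cingulate", "middle_cingulate", "amygdala", "parahippocampal",
      "hippocampus", "hypothalamus", "olfactory_cortex",
      "posterior_cingulate", "retrosplenial", "orbitofrontal",
      "superior_temporal", "insula", "frontoparietal_operculum",
      "superior_frontal", "middle_frontal", "inferior_frontal",
      "superior_parietal", "inferior_parietal", "precuneus",
      "middle_temporal", "inferior_temporal", "occipital",
      "thalamus", "globus_pallidus"), each = 2), c("L", "R")),
    "pons", "midbrain", "medulla"))
  expect_identical(union_rois, golden)
})

test_that("malformed pathway configs are rejected by name", {
  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.yaml")
  writeLines(c("pathways:",
               "  - name: p1",
               "    rois:",
               "      - {name: amygdala_L, laterality: left}",
               "      - {name: amygdala_L, laterality: left}"), dup)
  expect_error(loadPathwayConfig(dup), "duplicate ROI")

  empty <- file.path(dir, "empty.yaml")
  writeLines(c("pathways:",
               "  - name: p1",
               "    rois: []"), empty)
  expect_error(loadPathwayConfig(empty), "")

  expect_error(loadPathwayConfig(file.path(dir, "nope.yaml")), "exist")
})

test_that("a single-ROI pathway loads but persistence rejects it downstream", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "one.json")
  writeLines('{"pathways": [{"name": "tiny", "rois": [{"name": "pons", "laterality": "midline"}]}]}',
             cfg)
  paths <- loadPathwayConfig(cfg)
  expect_length(roiNames(paths$tiny), 1L)
  x <- UptakeMatrix(matrix(rnorm(20), 5, 4,
                           dimnames = list(NULL, c("pons", "a", "b", "c"))))
  sub <- uptakeValues(x)[, "pons", drop = FALSE]
  d <- matrix(0, 1, 1, dimnames = list("pons", "pons"))
  expect_error(persistentHomology(DistanceMatrix(d)), "at least 2")
})

test_that("subject tables round-trip bit-identically through write/read", {
  set.seed(21)
  spec <- syntheticSpec("g", 7, c(A = 3, B = 2), within = 0.5,
                        between = 0.1, seed = 5)
  x <- generateCohort(spec)$g
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    writeSubjectTable(x, path)
    y <- readSubjectTable(path, groupLabel = "g")
    expect_identical(unname(uptakeValues(y)), unname(uptakeValues(x)))
    expect_identical(roiNames(y), roiNames(x))
  }
})

test_that("defective tables are rejected with cell locations", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(c("a,b", "1,2", ",3", "4,5"), bad)
  expect_error(readSubjectTable(bad), "row 2, column 'a'")

  nonnum <- file.path(dir, "nonnum.csv")
  writeLines(c("a,b", "1,2", "3,x", "4,5"), nonnum)
  expect_error(readSubjectTable(nonnum), "row 2, column 'b'")

  dupcol <- file.path(dir, "dup.csv")
  writeLines(c("a,a", "1,2", "3,4", "5,6"), dupcol)
  expect_error(readSubjectTable(dupcol), "duplicate column")

  # transposed table (fewer than 3 rows) is refused
  wide <- file.path(dir, "wide.csv")
  writeLines(c("s1,s2,s3,s4,s5", "1,2,3,4,5", "6,7,8,9,10"), wide)
  expect_error(readSubjectTable(wide), "transposed|at least 3")
})

test_that("pathway extraction selects columns in pathway order and composes", {
  vals <- matrix(seq_len(30), 5, 6,
                 dimnames = list(NULL, c("r1", "r2", "r3", "r4", "r5", "r6")))
  x <- UptakeMatrix(vals, "g")

  p3 <- Pathway("p3", c("r5", "r2", "r6"))
  sub <- extractPathway(x, p3)
  expect_equal(roiNames(sub), c("r5", "r2", "r6"))
  expect_equal(unname(uptakeValues(sub)), unname(vals[, c("r5", "r2", "r6")]))
  expect_equal(nSubjects(sub), 5L)

  # identity extraction
  pall <- Pathway("all", colnames(vals))
  expect_equal(uptakeValues(extractPathway(x, pall)), uptakeValues(x))

  # composition: extracting a sub-pathway of an extraction equals one step
  p2 <- Pathway("p2", c("r6", "r2"))
  expect_equal(uptakeValues(extractPathway(sub, p2)),
               uptakeValues(extractPathway(x, p2)))

  expect_error(extractPathway(x, Pathway("p", c("r2", "missing_roi"))),
               "missing_roi")
})
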