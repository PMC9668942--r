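# Characterization surfaces: per-cluster time courses, at-biopsy table,
# disease crosstab, severity ordering, and the likelihood contour grid.

planted_assignment <- assignment_from_labels

test_that("disease crosstab reproduces a worked micro-example and reconciles margins", {
  df <- rbind(complete_long("M1", disease = "MCD"),
              complete_long("M2", disease = "MCD"),
              complete_long("M3", disease = "MN"))
  coh <- manual_cohort(df)
  asg <- planted_assignment(coh, labels = c("C1", "C1", "C2"))
  tab <- disease_crosstab(coh, asg)
  expect_equal(unname(tab["MCD", c("C1", "C2")]), c(2, 0), ignore_attr = TRUE)
  expect_equal(unname(tab["MN", c("C1", "C2")]), c(0, 1), ignore_attr = TRUE)
  expect_equal(unname(tab["Total", "Total"]), 3, ignore_attr = TRUE)
  # random larger case: all margins reconcile
  coh2 <- generate_cohort(make_default_archetypes(), 120, seed = 31)
  asg2 <- planted_assignment(coh2)
  tab2 <- disease_crosstab(coh2, asg2)
  expect_equal(unname(tab2["Total", "Total"]), 120, ignore_attr = TRUE)
  inner <- tab2[rownames(tab2) != "Total", colnames(tab2) != "Total",
                drop = FALSE]
  expect_equal(unname(rowSums(inner)), unname(tab2[rownames(tab2) != "Total",
                                                   "Total"]))
  expect_equal(unname(colSums(inner)), unname(tab2["Total",
                                                   colnames(tab2) != "Total"]))
  # unknown disease label errors
  coh3 <- coh
  coh3$info$disease[1] <- "unknown_gn"
  expect_error(disease_crosstab(coh3, asg), "unknown_gn")
})

test_that("trajectory means are exact for constant clusters and order-invariant", {
  df <- complete_long(c("T1", "T2"), value_fun = function(id, m, it) 2)
  coh <- manual_cohort(df)
  asg <- planted_assignment(coh, labels = c("C1", "C1"))
  tm <- trajectory_means(coh, asg)
  expect_true(all(tm$mean == 2))
  expect_true(all(tm$sd == 0))
  expect_equal(nrow(tm), 25L)            # 5 items x 5 visits, single cluster
  expect_setequal(unique(tm$month), visit_months())
  # permuting patient order leaves the profile unchanged
  coh_perm <- manual_cohort(df[rev(seq_len(nrow(df))), ])
  tm2 <- trajectory_means(coh_perm, planted_assignment(coh_perm,
                                                       labels = c("C1", "C1")))
  expect_equal(tm2, tm)
  # an id missing from the cohort is an error
  asg_bad <- asg
  asg_bad$ids <- c("T1", "TX")
  expect_error(trajectory_means(coh, asg_bad), "TX")
})

test_that("low-noise planted clusters recover the archetype visit means", {
  arch <- scale_archetype_noise(make_default_archetypes(),
                                baseline_scale = 0.25, visit_scale = 0.25)
  coh <- generate_cohort(arch, 2000, seed = 32)
  tm <- trajectory_means(coh, planted_assignment(coh))
  for (k in names(arch)) {
    a <- arch[[k]]
    for (it in clinical_items()) {
      row <- tm[tm$cluster == k & tm$item == it, ]
      expected <- a$baseline_mean[[it]] *
        a$course_multiplier[it, paste0("m", row$month)]
      if (it %in% c("hematuria", "proteinuria")) {
        # grid rounding moves grade means at most half a step
        expect_true(all(abs(row$mean - expected) <= 0.5 + 1e-9))
      } else {
        se <- row$sd / sqrt(row$n)
        expect_true(all(abs(row$mean - expected) <= 3 * se + 0.02))
      }
    }
  }
})

test_that("baseline table formats mean (SD) per cluster and omits empty clusters", {
  df <- complete_long("B1", value_fun = function(id, m, it)
    if (it == "creatinine") 1 else 2)
  coh <- manual_cohort(df)
  asg <- planted_assignment(coh, labels = "C1")
  tab <- baseline_table(coh, asg)
  expect_equal(tab[tab$item == "creatinine", "C1"], "1.00 (0.00)")
  expect_equal(colnames(tab), c("item", "C1", "Total"))
  # a bigger cohort: Total column equals the pooled summary
  coh2 <- generate_cohort(make_default_archetypes(), 300, seed = 33)
  tab2 <- baseline_table(coh2, planted_assignment(coh2))
  base <- coh2$data[coh2$data$visit_month == 0, ]
  pooled <- mean(base$value[base$item == "upcr"])
  expect_equal(unname(attr(tab2, "mean")["upcr", "Total"]), pooled)
  expect_equal(colnames(tab2), c("item", "C1", "C2", "C3", "C4", "Total"))
})

test_that("severity ranks clusters by month-24 creatinine with documented tie-breaks", {
  # planted default archetypes: C4 must rank last
  coh <- generate_cohort(make_default_archetypes(), 205, seed = 34)
  prof <- cluster_profile(coh, planted_assignment(coh))
  expect_equal(unname(prof$severity["C4"]), 4L)
  expect_setequal(prof$severity, 1:4)                   # bijection
  expect_equal(canonical_severity_order(prof), prof$severity)  # stable
  # all clusters identical: ranks follow original order
  traj <- data.frame(cluster = c("A", "B", "C"), item = "creatinine",
                     month = 24L, mean = 1, sd = 0, n = 5)
  expect_equal(canonical_severity_order(traj), c(A = 1L, B = 2L, C = 3L))
  # ties on creatinine break by month-24 UPCR
  traj2 <- rbind(traj,
                 data.frame(cluster = c("A", "B", "C"), item = "upcr",
                            month = 24L, mean = c(3, 2, 1), sd = 0, n = 5))
  expect_equal(canonical_severity_order(traj2), c(A = 3L, B = 2L, C = 1L))
  # single cluster
  expect_equal(canonical_severity_order(traj[1, ]), c(A = 1L))
  expect_error(canonical_severity_order(traj[traj$item == "upcr", ]),
               "month-24 creatinine")
})

test_that("likelihood contour grids equal direct evaluation and locate the mode", {
  model <- structure(list(K = 1L, weights = 1, means = matrix(c(0.5, -0.25), 1),
                          covariances = array(diag(2), c(2, 2, 1))),
                     class = "ns_gmm")
  ctr <- likelihood_contours(model, bounds = c(-2, 2, -2, 2),
                             resolution = 21L)
  expect_equal(dim(ctr$loglik), c(21L, 21L))
  # grid values equal per-node evaluation
  nodes <- as.data.frame(ctr)
  direct <- apply(cbind(nodes$z1, nodes$z2), 1, function(p)
    max(component_log_likelihood(model, p)))
  expect_equal(nodes$loglik, direct, tolerance = 1e-12)
  # maximum attained at the node nearest the mean
  peak <- nodes[which.max(nodes$loglik), ]
  grid_step <- diff(ctr$z1[1:2])
  expect_lt(abs(peak$z1 - 0.5), grid_step)
  expect_lt(abs(peak$z2 + 0.25), grid_step)
  # enlarging bounds never increases interior values
  big <- likelihood_contours(model, bounds = c(-4, 4, -4, 4),
                             resolution = 41L)
  expect_lte(max(big$loglik), max(ctr$loglik) + 1e-9)
  expect_error(likelihood_contours(model, bounds = c(1, 1, -2, 2)), "bounds")
  expect_error(likelihood_contours(model, bounds = c(-2, 2, -2, 2),
                                   resolution = 1L), "resolution")
})
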