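# sitrack

Tracking-by-detection of surgical instruments in robotic-surgery video, and
quantitative surgical-skill assessment from the resulting instrument motion.

Rating a surgeon with OSATS/GEARS-style rubrics takes an expert watching the
whole recording. Most of what those rubrics reward is visible in how the
instruments move, so `sitrack` automates the chain from video to a skill
class:

```
detections (box + mask + confidence)
  → non-maximum suppression
  → SORT-style tracker  (constant-velocity Kalman filter; association by
       λ·Mahalanobis + (1−λ)·appearance cosine cost, Hungarian assignment,
       χ²(0.95, 4 df) gating; ≤ 3 confirmed instrument tracks)
  → cascaded re-identification  (offline appearance gallery, then an online
       bag-of-visual-words model trained on the previous 10 frames when an
       identity change is predicted)
  → arm-indicator recognition  (template matching; camera-motion and
       inactive-arm samples are flagged invalid for motion)
  → tip localization + mm calibration  (known 8 mm shaft width)
  → nine motion metrics  (time to completion, out-of-view events,
       collisions, economy of motion, average speed, number of movements,
       economic factor, instrument changes, laparoscopy usage)
  → novice / skilled / expert classifier  (linear, Gaussian-kernel SVM or
       Gini random forest; SMOTE inside CV folds; 5-fold tuned)
```

Real surgical video cannot ship with a package, so a synthetic-scene
simulator with complete ground truth (`generateScene()`, `randomScene()`,
`generateSkillCohort()`) makes every stage testable: rigid elongated
instruments pivoting about trocar points, crossings, exit/re-entry events,
camera moves with indicator overlays, and skill-dependent motion
statistics. See the vignette (`vignettes/instrument-tracking.Rmd`) for the
methods and design decisions.

## Worked example

```r
library(sitrack)
scene <- randomScene(nInstruments = 3, nFrames = 500, seed = 2)
res   <- runPipeline(scene)        # detect → track → reid → tips → metrics
res$metrics
#>   timeToCompletionS outOfViewCount collisionCount economyOfMotionMm
#> 1             21.74              3              2               916
#>   averageSpeedMmS movementCount economicFactor instrumentChangeCount
#> 1           22.41            25         0.8407                     0
#>   laparoscopyCount laparoscopyDurationS
#> 1                1                0.913
```

The 500-frame scene spans 21.7 s at 23 fps; the tips travelled 916 mm in
total at 22.4 mm/s across 25 distinct movements; all three scheduled
out-of-view events and both instrument crossings were recovered, and one
laparoscope move of 0.91 s was recognized from the camera-arm indicator.
Scoring the same run against ground truth:

```r
evaluateTracking(res, scene)
#> EvalReport: RMSE 0.000 mm over 88 samples
#>   AUC: 1 mm=1.000, 2 mm=1.000, 5 mm=1.000
#>   Pearson r: x=1.000 y=1.000; identity switches: 0
```

Zero tip error at the 2 samples/s ground-truth cadence, perfect tolerance
AUCs and no identity switches — the algorithmic chain is exact when the
detections are. A skill model on a synthetic 52-subject cohort (40 train,
12 test, 4 per class):

```r
co  <- generateSkillCohort(nPerClass = c(18, 17, 17), seed = 4)
cm  <- cohortMetrics(co)
# ... split 40/12, normalize on the training fold, then:
fit <- trainSkillModel(norm$normalized, cm$labels[train],
                       kind = "random_forest", seed = 1)
confusionMatrix(cm$labels[test], predictSkill(fit, newMetrics))
#>          predicted
#> truth     novice skilled expert
#>   novice       4       0      0
#>   skilled      0       4      0
#>   expert       0       0      4
```

A thin command-line front end over these functions is installed at
`inst/scripts/sitrack.R` (subcommands `simulate`, `run`, `evaluate`,
`skill-train`, `skill-predict`).

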