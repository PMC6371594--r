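# sharedreach

Desk-scale simulator and library for a **vision-aided brain–machine
interface (BMI) training system** for robotic arm reaching. People with
cervical spinal cord injury can, in principle, drive a robotic arm with
hand-velocity vectors decoded from noninvasive EEG, but decoded velocities
are far too noisy for reliable reaching on their own. A shared controller
can close the gap: an RGB-D camera detects candidate target objects on the
table, and an attractive artificial potential nudges every decoded command
toward whichever target the user currently appears to intend — without any
target being preprogrammed, and while preserving the user's volition.

`sharedreach` implements that whole rig in software, for controller and
parameter studies without camera, robot, or EEG hardware:

- **Imaging** — green-target detection in `480 × 640` RGB images by
  colour-ratio segmentation (`G/(R+G+B) > 0.5`), 3×3 erosion, and divisive
  hierarchical clustering that splits any pixel cluster with an axis
  standard deviation ≥ 20 px, so the number of targets need not be known
  in advance.
- **Calibration** — metric localization through three calibrations: the
  least-squares affine RGB→depth pixel map *B* (`D = [A 1]B`), the linear
  depth law `distance = 61.5·index + 0.1046` m, distance-scaled
  pixel-to-metre coefficients, and the fixed homogeneous Kinect→robot
  transform.
- **Kinematics** — closed-form forward and inverse kinematics of the
  3-DOF anthropomorphic positioning chain (link lengths
  `a₂ = 0.41` m, `a₃ = 0.44` m), both elbow branches.
- **Shared control** — per step: infer the intended target as the one with
  the smallest angle to the decoded velocity `Δx_n`; form the
  attraction-driven ideal vector `Δx_i = x_e(q + f_t) − x_e(q)` (which, with
  unit stiffness on the intended target only, points exactly at it); blend
  `Δx_k = 1.5[α‖Δx_n‖·unit(Δx_i) + (1−α)Δx_n]`; apply inertia
  `s_k = βΔx_k + (1−β)Δx_{k−1}`; gate out commands that retreat toward the
  start or point ≥ 90° away from the intended target.
- **Synthetic data** — scene renderer that inverts the calibration model,
  and a decoded-velocity generator emulating noisy directional reaches
  (4 directions × 30 trials by default).
- **Evaluation** — shortest waypoint distance to each target, percent
  decrease versus the uncompensated integrated trajectory, the full
  `(α, β) ∈ {0.05, …, 1.00}²` sweep, a one-tailed pooled two-sample t-test
  of intended vs nonintended improvement, and the chance level
  `100 / n_targets` %.

## Worked example

```r
library(sharedreach)

## perception: render a 3-target scene, detect, localize
scene    <- render_scene(scene_spec(n_targets = 3, seed = 42))
clusters <- detect_targets(scene$rgb)
clusters_to_table(clusters)
#>   cluster_id centroid_x centroid_y n_pixels    std_x    std_y
#> 1          1   250.8862   201.0881      738 7.203436 8.153114
#> 2          2   332.0350   283.6050      714 7.101123 8.002855
#> 3          3   377.3094   219.1439      695 7.018423 7.880366
localize_targets(clusters, scene$depth)
#>    target_id         x           y           z frame
#> x          1 0.1716521 -0.15451016  0.12730308 robot
#> x1         2 0.1546255  0.02730228 -0.03816486 robot
#> x2         3 0.1438209  0.13120970  0.09263580 robot

## control: one noisy decoded reach under shared control
lay    <- default_reach_layout()
trials <- generate_trials(trajectory_spec(seed = 7),
                          lay$targets, lay$start_position)
trial  <- run_trial(trials[[1]], lay$targets,
                    shared_control_params(alpha = 0.6, beta = 0.6),
                    lay$start_config)
summary(trial)
#> Shared-control trial: 42 steps, alpha = 0.60, beta = 0.60
#>   start (0.400, 0.000, -0.100) -> end (0.650, 0.253, 0.038) m
#>   gated steps: 2, clamped steps: 0, reached: 1

## evaluation over the 120-trial ensemble
res <- evaluate_trials(trials, lay$targets,
                       shared_control_params(0.6, 0.6), lay$start_config)
mean(res$decrease_intended)     # 80.93 (%)
mean(res$decrease_nonintended)  #  3.36 (%)
chance_level(4)                 # 25 (%)
```

The detected clusters recover each rendered ball (their erosion-shrunk
disks are ~7–8 px in spread, comfortably below the 20 px split threshold),
and the localized positions agree with the scene's ground truth to well
under a centimetre. In the control example the shortest distance to the
*intended* target shrinks by ~81 % on average relative to the raw
integrated decoded trajectory, while the distances to the three
*nonintended* targets barely move — the controller reaches selectively,
not indiscriminately. `sweep_shared_control()` repeats this over the full
blending-parameter lattice and `plot()` draws the resulting surface.

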