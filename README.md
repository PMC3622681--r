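# ofcbmi

Two-stage neural decoding of reach target and trajectory for
brain-machine interfaces (BMIs), built around an optimal feedback control
model of reaching, with a closed-loop simulator of the instructed-delay
center-out task so the entire stack runs on synthetic spikes.

The package is for computational neuroscientists and BMI engineers who
want a complete, testable reference implementation of point-process
decoding with a goal-directed prior: encoding-model fitting, discrete
target classification, recursive Bayesian trajectory estimation, standard
baselines, and closed-loop evaluation, all driven by 5 ms binned binary
spike trains.

## The method

**Stage 1 — target.** Delay-period spiking of neuron $c$ is a homogeneous
Poisson process with target-dependent rate $\lambda_c(m)$.  Over the 800 ms
decoding window the ensemble Bernoulli log-likelihood of target $m$ is

$$\ell(m)=\sum_c\sum_t \Delta N_{c,t}\log(\lambda_c(m)\Delta)
+(1-\Delta N_{c,t})\log(1-\lambda_c(m)\Delta),$$

and the decoder takes the argmax.

**Stage 2 — trajectory.** The kinematic state
$x=(p_x,p_y,v_x,v_y,f_x,f_y)$ follows a muscle-like linear plant
$x_t=Ax_{t-1}+Bu_t+w_t$; the subject's control is modeled as the LQG
optimal feedback law $u_t=-L_t(x_{t-1}-x^\*)$ toward the stage-1 target
$x^\*$, with gains $L_t$ from a backward Riccati recursion.  Spikes enter
through log-linear tuning $\lambda_c=\exp(\alpha_c+\beta_c'(p,v))$ via a
point process filter in information form (prediction through the closed
loop, innovation $\Delta N_c-\lambda_c\Delta$).  Since the movement
duration $T$ is the subject's choice, a bank of filters over a coarse
duration grid runs in parallel, each weighted by its per-bin predictive
likelihood; the estimate is the weight-averaged posterior mean
(FC-P-PPF).  Removing the control term ($B=0$) gives the random-walk
ablation (RW-PPF); a ridge regression of position on 100 ms sliding-window
firing-rate history is the linear baseline.

The simulator closes the loop: a synthetic population (target-tuned and
kinematically tuned fractions matching typical premotor recordings) spikes
in response to the subject's intended state, whose position component is
slaved to the *decoded* cursor — perfect visual feedback — while any
decoder with a per-bin interface moves the cursor.

## Worked example

```r
library(ofcbmi)

cfg  <- make_center_out_config()          # 4 targets, 5 ms bins, 3 s timeout
sys  <- discretize_plant(plant_params())  # muscle-like plant, ZOH at 5 ms
grid <- duration_grid()                   # {0.4, 0.6, 0.8, 1.0, 1.2} s

pop   <- make_population(seed = 7)        # 20 neurons, ground truth known
train <- run_session(89, "manual", pop, cfg, sys, grid, seed = 21)
train$summary$accuracy_pct
#> [1] 87.64045

tm <- fit_target_model(train$records, cfg)
km <- fit_kinematic_model(train$records)$model
100 * target_accuracy_loo(train$records, cfg)   # stage-1, leave-one-out
#> [1] 79.77528

two <- run_session(100, "closed_loop", pop, cfg, sys, grid,
                   decoder = make_two_stage_decoder(tm, km, cfg, sys, grid),
                   seed = 33)
rw  <- run_session(100, "closed_loop", pop, cfg, sys, grid,
                   decoder = make_rw_ppf_decoder(km, sys), seed = 33)
c(two = two$summary$accuracy_pct, rw = rw$summary$accuracy_pct)
#>  two   rw 
#>   84   56
```

An 89-trial training session gives a well-behaved manual subject (87.6%
task success), stage-1 target prediction decodes at 79.8% against a 25%
chance level, and over 100 paired closed-loop trials the two-stage decoder
(84%) clearly outperforms the target-blind random-walk filter (56%).

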