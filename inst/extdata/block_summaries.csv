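# Group-level block summaries from the five Libet-clock experiments (synthetic-generator calibration fixture).
# One row per experiment x condition x judged event. Means/SDs are participant-level (ms);
# shift = operant - baseline judgment error. experiment: 1-2 clock speed, 3-4 clock markings, 5 hand length.
experiment,condition,period_ms,event,baseline_mean,baseline_sd,operant_mean,operant_sd,shift_mean,shift_sd,n_participants
1,speed_1280,1280,action,-23.25,68.30,13.54,79.20,36.80,42.92,39
1,speed_1280,1280,tone,28.09,56.65,-45.69,100.06,-73.79,76.52,39
1,speed_2560,2560,action,-7.72,72.28,18.90,84.81,26.62,35.78,39
1,speed_2560,2560,tone,16.29,75.17,-44.19,108.28,-60.49,82.62,39
1,speed_5120,5120,action,11.75,72.61,47.13,78.62,35.38,41.71,39
1,speed_5120,5120,tone,26.79,79.97,-16.09,124.52,-42.88,97.44,39
2,speed_1280,1280,action,-28.45,55.55,-6.56,57.58,21.89,38.87,40
2,speed_1280,1280,tone,-30.79,52.63,-110.71,114.46,-79.91,92.08,40
2,speed_2560,2560,action,-38.57,70.07,-8.77,64.29,29.80,38.66,40
2,speed_2560,2560,tone,-38.31,62.10,-103.15,133.59,-64.84,100.33,40
2,speed_5120,5120,action,-9.82,77.43,13.91,87.33,23.74,58.18,40
2,speed_5120,5120,tone,-33.63,73.19,-65.43,164.59,-31.80,133.47,40
3,markings_5,2560,action,-2.69,89.34,20.60,87.22,23.29,41.81,39
3,markings_5,2560,tone,5.03,75.54,-86.33,136.47,-91.36,113.65,39
3,markings_5_1,2560,action,-22.73,82.24,9.80,86.86,32.54,35.85,39
3,markings_5_1,2560,tone,4.33,71.36,-87.98,135.83,-92.31,114.57,39
4,markings_none,2560,action,-15.30,45.71,4.65,39.86,19.96,42.29,36
4,markings_none,2560,tone,-29.23,55.12,-138.56,104.81,-109.32,113.28,36
4,markings_30,2560,action,-18.94,45.59,1.04,41.29,19.98,34.20,36
4,markings_30,2560,tone,-25.27,48.99,-145.47,106.49,-120.20,103.31,36
4,markings_15,2560,action,-22.54,54.23,2.51,57.48,25.05,37.50,36
4,markings_15,2560,tone,-32.69,56.55,-141.47,115.36,-108.77,101.71,36
5,hand_8mm,2560,action,-4.62,51.55,24.83,67.11,29.45,39.72,39
5,hand_8mm,2560,tone,-17.67,48.97,-107.05,115.92,-89.38,92.57,39
5,hand_10mm,2560,action,-17.58,56.82,16.56,63.35,34.14,56.30,39
5,hand_10mm,2560,tone,-28.04,57.73,-118.48,110.24,-90.44,100.84,39
5,hand_13mm,2560,action,-10.26,43.66,12.61,48.14,22.88,34.98,39
5,hand_13mm,2560,tone,-40.07,40.10,-117.14,112.80,-77.06,95.10,39
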