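r_cm	0	10	20	30	40	50	60	70	80	90	100	110	120	130	140	150	160	170	180
0.25	0.63	0.639	0.6651	0.7061	0.7585	0.8176	0.878	0.9335	0.9775	1	0.9775	0.9335	0.878	0.8176	0.7585	0.7061	0.6651	0.639	0.63
0.5	0.6398	0.6485	0.6739	0.7139	0.7648	0.8224	0.8812	0.9353	0.9781	1	0.9781	0.9353	0.8812	0.8224	0.7648	0.7139	0.6739	0.6485	0.6398
1	0.6584	0.6667	0.6908	0.7287	0.777	0.8316	0.8873	0.9386	0.9793	1	0.9793	0.9386	0.8873	0.8316	0.777	0.7287	0.6908	0.6667	0.6584
2	0.6925	0.7	0.7217	0.7558	0.7993	0.8484	0.8986	0.9448	0.9813	1	0.9813	0.9448	0.8986	0.8484	0.7993	0.7558	0.7217	0.7	0.6925
3	0.7228	0.7295	0.7491	0.7798	0.819	0.8633	0.9086	0.9502	0.9832	1	0.9832	0.9502	0.9086	0.8633	0.819	0.7798	0.7491	0.7295	0.7228
5	0.7734	0.7789	0.7949	0.82	0.8521	0.8883	0.9253	0.9593	0.9862	1	0.9862	0.9593	0.9253	0.8883	0.8521	0.82	0.7949	0.7789	0.7734
8	0.8298	0.8339	0.8459	0.8648	0.8889	0.9161	0.9439	0.9694	0.9897	1	0.9897	0.9694	0.9439	0.9161	0.8889	0.8648	0.8459	0.8339	0.8298
10	0.8576	0.861	0.8711	0.8869	0.907	0.9298	0.953	0.9744	0.9914	1	0.9914	0.9744	0.953	0.9298	0.907	0.8869	0.8711	0.861	0.8576
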