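x,y,duration,line
79.38321050563827,80.94119969551758,279.3416727270423,0
114.20050467476248,73.89833557060047,227.9243212782652,0
192.2132479239255,71.86759612105041,136.17038957709818,0
294.09053735220806,76.70915888232724,171.33672928815568,0
87.3659500753507,124.59483618835753,138.7693692550822,1
112.13018411891535,132.20485328151432,176.32996817803442,1
161.89968630420043,124.88227999180049,168.9816661387938,1
130.31962096504867,177.06921808735234,202.10579365721176,2
207.8185399165377,175.084006476342,154.45391757237772,2
272.03978454321623,172.7701803733528,207.90143862020375,2
81.9754403614439,225.56637689854304,167.27076780405912,3
107.79983106693253,219.58512411332688,288.3643634686323,3
151.96056455634533,229.39666458468866,235.83537380086028,3
204.91261444082483,225.4597600146357,245.50871147476136,3
204.28076765434815,231.51783501108645,219.20926789131724,3
301.1336366740987,226.426528586699,284.1088040259709,3
113.85075763082132,272.87016070723456,168.21317730255114,4
163.96465541878715,276.8321790604672,176.9177634819717,4
205.6991313827224,272.19770710506725,271.6141119270832,4
262.98888245290146,271.2390997992827,167.46518233448165,4
113.56803131820634,325.8743387065524,189.63096281990173,5
161.46864775596185,323.6701243803447,180.35960352790082,5
203.6880763807334,325.00331605489487,184.00035657257465,5
269.56744032334535,325.223023972455,186.04433485117204,5
302.1192647766322,323.2314371614358,224.70941656339136,5
341.45823360858486,323.2939938015445,191.13347588651968,5
370.5025224613957,324.5944641546285,174.70212689428712,5
153.72610728312284,378.5342609897196,267.1519412585206,6
221.1479987083003,370.4292995987107,189.27102957265657,6
280.2417178423144,376.78183856288524,191.02217349783064,6
154.39591815806926,425.99885111364057,194.9904629393219,7
217.50780437663198,428.18929951182906,235.63331535257026,7
147.98052183520048,474.0874482290971,196.32177979368367,8
206.00479793315753,476.11005642974885,198.1182914266476,8
228.59624405652283,475.8012963723167,165.91697606221715,8
118.88117044232786,523.3724399070251,183.78648638768405,9
233.34354102937505,528.6236034179495,203.00802202172576,9
113.9222340949811,578.4812078470849,170.5552756870168,10
72.1628290142864,677.100640948545,226.57480963162863,12
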